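# Monte-Carlo oracle: simulate the exact stochastic model whose moments the
# rewards recursion computes, path by path.  Deliberately independent of the
# analytic code so the two routes can be checked against each other.

#' Simulate healthy years lived after 60
#'
#' Forward simulation of the two-process model: an individual alive at
#' exact age 60 survives each year \eqn{x \to x+1} with probability
#' \eqn{1 - q_x}, and each year contributes a Bernoulli(\eqn{h_x}) healthy
#' reward under the chosen timing convention.  Healthy years are capped at
#' 30 (the age-90 limit), and the exit age is 60 + accumulated healthy
#' years.  Serves as an independent check of [mcwr_moments()] and of the
#' maximum-entropy reconstruction.
#'
#' @param mortality Data frame with columns `age`, `qx` covering ages 60--89.
#' @param prevalence Data frame with columns `age`, `hx` covering ages 60--89.
#' @param convention Reward timing: `"occupancy"` (the reward for year
#'   `[x, x+1)` is earned by anyone alive at exact age `x`) or
#'   `"survived-year"` (earned only if the year is survived).
#' @param condition_on_healthy_at_60 If `TRUE` (default), the age-60 reward
#'   probability is replaced by 1: the population is people healthy at 60.
#' @param n_sim Number of simulated individuals (>= 1).
#' @param seed Integer seed.
#' @return An object of class `hl_oracle`: a list with `moments` (tibble
#'   with `order`, `value`, `se` for raw moments 1--3 of healthy years),
#'   `pmf` (tibble with `age`, `p`, `se` on ages 60--90), `n_sim`, `seed`,
#'   `convention`, `condition_on_healthy_at_60`.
#' @examples
#' mort <- sim_mortality_schedule()
#' prev <- sim_prevalence_schedule()
#' orc <- simulate_healthy_years(mort, prev, n_sim = 1e4, seed = 7)
#' orc$moments
#' @export
simulate_healthy_years <- function(mortality, prevalence,
                                   convention = c("occupancy", "survived-year"),
                                   condition_on_healthy_at_60 = TRUE,
                                   n_sim = 1e5, seed = 1L) {
  convention <- match.arg(convention)
  qx <- check_schedule(mortality, "qx")
  hx <- check_schedule(prevalence, "hx", lower = 0, upper = 1, upper_open = FALSE)
  if (n_sim < 1) abort("`n_sim` must be >= 1.", class = "hl_input_error")
  n_sim <- as.integer(round(n_sim))

  sx <- 1 - qx
  if (condition_on_healthy_at_60) hx[1] <- 1
  n_age <- length(qx)

  chunk <- 100000L
  pow_sums <- numeric(6)          # running sums of HY^1 .. HY^6
  counts <- numeric(31)           # exit ages 60..90
  done <- 0L

  with_seed(seed, {
    while (done < n_sim) {
      m <- min(chunk, n_sim - done)
      surv <- matrix(runif(m * n_age), m, n_age) <
        matrix(sx, m, n_age, byrow = TRUE)
      rew <- matrix(runif(m * n_age), m, n_age) <
        matrix(hx, m, n_age, byrow = TRUE)
      alive_through <- row_cumall(surv)   # alive at end of year j
      if (convention == "occupancy") {
        # alive at exact age x_j: shift the cumulative survival right by one
        at_risk <- cbind(TRUE, alive_through[, -n_age, drop = FALSE])
      } else {
        at_risk <- alive_through
      }
      hy <- rowSums(at_risk & rew)
      for (k in 1:6) pow_sums[k] <- pow_sums[k] + sum(hy^k)
      counts <- counts + tabulate(hy + 1L, nbins = 31L)
      done <- done + m
    }
  })

  n <- n_sim
  means <- pow_sums / n     # E[HY^k], k = 1..6
  se_k <- function(k) {
    v <- means[2 * k] - means[k]^2
    sqrt(max(v, 0) / n)
  }
  p_hat <- counts / n
  structure(
    list(
      moments = tibble::tibble(order = 1:3, value = means[1:3],
                               se = vapply(1:3, se_k, numeric(1))),
      pmf = tibble::tibble(age = 60:90, p = p_hat,
                           se = sqrt(pmax(p_hat * (1 - p_hat), 0) / n)),
      n_sim = n, seed = seed, convention = convention,
      condition_on_healthy_at_60 = condition_on_healthy_at_60
    ),
    class = "hl_oracle"
  )
}

# Row-wise running AND for a logical matrix (column loop: fast, no deps).
row_cumall <- function(x) {
  out <- x
  for (j in seq_len(ncol(x))[-1]) out[, j] <- out[, j - 1L] & x[, j]
  out
}

#' @export
print.hl_oracle <- function(x, ...) {
  cat(sprintf(
    "<hl_oracle> %s simulated paths (%s timing%s)\n",
    format(x$n_sim, big.mark = ","), x$convention,
    if (x$condition_on_healthy_at_60) ", conditioned on healthy at 60" else ""))
  m <- x$moments
  cat(sprintf("  raw moments: m1 = %.4f (SE %.1e), m2 = %.3f, m3 = %.2f\n",
              m$value[1], m$se[1], m$value[2], m$value[3]))
  invisible(x)
}
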