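# Markov chain with rewards: first three raw moments of healthy years
# lived after age 60, by scalar backward recursion.
#
# The chain runs over single ages 60..89 with survival s_x = 1 - q_x and an
# independent Bernoulli(h_x) healthy reward per year; anyone alive at the
# cap (age 90) is absorbed there, so total reward HY lies in [0, 30].
# Raw moments follow from E[(B + S R')^k] (occupancy timing) or
# E[S^k (B + R')^k] (survived-year timing) with B ~ Bern(h_x),
# S ~ Bern(s_x), R' the remaining reward, all independent.

mcwr_core <- function(qx, hx, convention = "occupancy",
                      condition_on_healthy_at_60 = TRUE) {
  n <- length(qx)
  sx <- 1 - qx
  if (condition_on_healthy_at_60) hx[1] <- 1
  m1 <- m2 <- m3 <- 0
  for (i in n:1) {
    h <- hx[i]; s <- sx[i]
    if (convention == "occupancy") {
      m3n <- h + 3 * h * s * m1 + 3 * h * s * m2 + s * m3
      m2n <- h + 2 * h * s * m1 + s * m2
      m1n <- h + s * m1
    } else {
      m3n <- s * (h + 3 * h * m1 + 3 * h * m2 + m3)
      m2n <- s * (h + 2 * h * m1 + m2)
      m1n <- s * (h + m1)
    }
    m1 <- m1n; m2 <- m2n; m3 <- m3n
  }
  c(m1 = m1, m2 = m2, m3 = m3)
}

#' Moments of healthy longevity via a Markov chain with rewards
#'
#' Computes the first three raw moments of healthy years lived after age
#' 60 from an age-specific mortality schedule and a healthy-prevalence
#' schedule, then completes them into mean, variance and skewness.  The
#' mean plus 60 is the healthy-life-expectancy (HLE) age; the standard
#' deviation is the inter-individual variation in healthy longevity
#' (SDHL).
#'
#' @inheritParams simulate_healthy_years
#' @param convention Reward timing, `"occupancy"` (default) or
#'   `"survived-year"`; see [simulate_healthy_years()] for the semantics.
#' @return An object of class `hl_moments` with raw moments `m1`--`m3`,
#'   `variance`, `mu3`, `skewness` (`NA` when the variance is degenerate),
#'   `hle` (= 60 + m1) and `sdhl`.  Use [tidy()] for a one-row tibble.
#' @examples
#' mom <- mcwr_moments(sim_mortality_schedule(), sim_prevalence_schedule())
#' tidy(mom)
#' @export
mcwr_moments <- function(mortality, prevalence,
                         convention = c("occupancy", "survived-year"),
                         condition_on_healthy_at_60 = TRUE) {
  convention <- match.arg(convention)
  qx <- check_schedule(mortality, "qx")
  hx <- check_schedule(prevalence, "hx", lower = 0, upper = 1, upper_open = FALSE)
  m <- mcwr_core(qx, hx, convention, condition_on_healthy_at_60)
  cm <- central_moments(m[["m1"]], m[["m2"]], m[["m3"]])
  structure(
    list(m1 = m[["m1"]], m2 = m[["m2"]], m3 = m[["m3"]],
         mean = m[["m1"]], variance = cm$variance, mu3 = cm$mu3,
         skewness = cm$skewness, degenerate = cm$degenerate,
         hle = 60 + m[["m1"]], sdhl = sqrt(cm$variance),
         convention = convention,
         condition_on_healthy_at_60 = condition_on_healthy_at_60),
    class = "hl_moments"
  )
}

#' Convert raw moments to central moments and shape summaries
#'
#' @param m1,m2,m3 First three raw moments of a nonnegative bounded
#'   variable (healthy years).
#' @param tol Degeneracy/feasibility tolerance on the variance.
#' @return A one-row tibble with `variance`, `mu3`, `skewness` and a
#'   `degenerate` flag; `skewness` is `NA` when `variance < tol`.
#' @export
central_moments <- function(m1, m2, m3, tol = 1e-12) {
  m1 <- as.numeric(m1); m2 <- as.numeric(m2); m3 <- as.numeric(m3)
  variance <- m2 - m1^2
  if (variance < -tol * max(1, m1^2)) {
    abort(sprintf("Infeasible moments: m2 (%.6g) < m1^2 (%.6g).", m2, m1^2),
          class = "hl_infeasible_error")
  }
  variance <- max(variance, 0)
  mu3 <- m3 - 3 * m1 * m2 + 2 * m1^3
  degenerate <- variance < tol
  skewness <- if (degenerate) NA_real_ else mu3 / variance^1.5
  tibble::tibble(variance = variance, mu3 = mu3, skewness = skewness,
                 degenerate = degenerate)
}

#' Sullivan-type healthy life expectancy
#'
#' Direct summation \eqn{\sum_x \ell_x h_x} with \eqn{\ell_{60} = 1} and
#' \eqn{\ell_{x+1} = \ell_x (1-q_x)}: the classical prevalence-weighted
#' person-years route to HLE.  Algebraically identical to the occupancy
#' first moment of [mcwr_moments()]; exposed as an independent check and a
#' familiar reference method.
#'
#' @inheritParams mcwr_moments
#' @return Expected healthy years after 60 (a single number).
#' @export
sullivan_hle <- function(mortality, prevalence, condition_on_healthy_at_60 = TRUE) {
  qx <- check_schedule(mortality, "qx")
  hx <- check_schedule(prevalence, "hx", lower = 0, upper = 1, upper_open = FALSE)
  if (condition_on_healthy_at_60) hx[1] <- 1
  lx <- cumprod(c(1, (1 - qx)[-length(qx)]))
  sum(lx * hx)
}

#' @export
print.hl_moments <- function(x, ...) {
  cat(sprintf("<hl_moments> %s timing%s\n", x$convention,
              if (x$condition_on_healthy_at_60) ", conditioned on healthy at 60" else ""))
  cat(sprintf("  HLE age %.2f (%.2f healthy years), SDHL %.3f, skewness %s\n",
              x$hle, x$mean, x$sdhl,
              if (is.na(x$skewness)) "undefined (degenerate)" else sprintf("%.3f", x$skewness)))
  invisible(x)
}

#' @describeIn mcwr_moments One-row tibble with `m1`--`m3`, `hle`, `sdhl`,
#'   `skewness`.
#' @param x An `hl_moments` object.
#' @param ... Unused.
#' @export
tidy.hl_moments <- function(x, ...) {
  tibble::tibble(m1 = x$m1, m2 = x$m2, m3 = x$m3, hle = x$hle,
                 sdhl = x$sdhl, skewness = x$skewness)
}

#' @describeIn mcwr_moments Convention and degeneracy flags.
#' @export
glance.hl_moments <- function(x, ...) {
  tibble::tibble(convention = x$convention,
                 condition_on_healthy_at_60 = x$condition_on_healthy_at_60,
                 degenerate = x$degenerate)
}
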