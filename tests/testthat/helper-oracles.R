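# Independent oracles and fixture builders, kept deliberately separate
# from the package's own algorithms.

# Exact exit-age pmf by forward dynamic programming over the state
# (alive, accumulated healthy years).  An independent route to the same
# stochastic model as the backward moment recursion and the Monte-Carlo
# simulator: mortality thins the alive mass, the Bernoulli reward shifts
# part of it up by one healthy year.
dp_exit_pmf <- function(qx, hx, convention = "occupancy",
                        condition_on_healthy_at_60 = TRUE) {
  if (condition_on_healthy_at_60) hx[1] <- 1
  n <- length(qx)
  alive <- c(1, numeric(n))   # index k+1 <-> k healthy years so far
  done <- numeric(n + 1)      # exited (died), by healthy years
  for (i in seq_len(n)) {
    h <- hx[i]; q <- qx[i]
    if (convention == "occupancy") {
      shifted <- c(0, head(alive * h, -1)) + alive * (1 - h)
      done <- done + shifted * q
      alive <- shifted * (1 - q)
    } else {
      done <- done + alive * q
      surv <- alive * (1 - q)
      alive <- c(0, head(surv * h, -1)) + surv * (1 - h)
    }
  }
  done + alive                # pmf of healthy years 0..n; exit age = 60 + HY
}

moments_from_pmf <- function(p, values = seq_along(p) - 1) {
  c(m1 = sum(p * values), m2 = sum(p * values^2), m3 = sum(p * values^3))
}

# Random but well-behaved synthetic schedules (Gompertz mortality,
# logistic prevalence), for property-style loops.
random_schedules <- function() {
  list(
    mortality = sim_mortality_schedule(a = runif(1, 0.002, 0.02),
                                       b = runif(1, 0.05, 0.12)),
    prevalence = sim_prevalence_schedule(x0 = runif(1, 68, 82),
                                         k = runif(1, 0.05, 0.3),
                                         floor = runif(1, 0, 0.3))
  )
}

with_seed_local <- function(seed, code) withr::with_seed(seed, code)

# Random normalized pmf on ages 60..90.
random_pmf <- function(concentration = 1) {
  w <- rgamma(31, concentration)
  tibble::tibble(age = 60:90, phloss = w / sum(w))
}

# Brute-force outsurvival probability P(X1 > X2) + P(X1 = X2)/2 by
# enumeration over all age pairs.
phi_brute <- function(p1, p2) {
  gt <- outer(60:90, 60:90, `>`)
  eq <- outer(60:90, 60:90, `==`)
  sum(outer(p1, p2) * gt) + sum(outer(p1, p2) * eq) / 2
}

# A small HMD-style 1x1 period life table written to a temp file.
write_toy_hmd <- function(path, years = 1990, qx_fun = function(age) 0.01,
                          ages = 0:110) {
  lines <- c("Toyland, Life tables (period 1x1), Males\tLast modified: 01 Jan 2020",
             "",
             "  Year          Age         mx       qx    ax      lx      dx      Lx       Tx     ex")
  for (y in years) {
    for (a in ages) {
      age_lab <- if (a == 110) "110+" else as.character(a)
      q <- if (a == 110) 1 else qx_fun(a)
      lines <- c(lines, sprintf("  %d    %s    %.5f  %.5f  0.50  100000  %d  99500  5000000  %.2f",
                                y, age_lab, q, q, round(1e5 * q), 80 - a / 2))
    }
  }
  writeLines(lines, path)
  path
}

# Orthonormal basis of the null space of a (full-row-rank) matrix.
null_space <- function(A) {
  qr_t <- qr(t(A))
  qr.Q(qr_t, complete = TRUE)[, (qr_t$rank + 1):nrow(t(A)), drop = FALSE]
}

# Shannon entropy of a pmf (0 log 0 = 0).
entropy_of <- function(p) -sum(ifelse(p > 0, p * log(p), 0))

point_mass_pmf <- function(age_at) {
  tibble::tibble(age = 60:90, phloss = as.numeric(60:90 == age_at))
}
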