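# Maximum-entropy reconstruction of the discrete exit-age distribution on
# ages 60..90 from the first three moments of healthy years.
#
# The entropy maximizer subject to three moment constraints is the
# exponential family p_x ∝ exp(l1 z_x + l2 z_x^2 + l3 z_x^3), with the age
# basis standardized to the target mean and SD for conditioning (a raw-age
# cubic spans ~2e5 and is numerically hazardous).  The multipliers solve
# the strictly convex dual  psi(l) = log Z(l) - <l, t>,  minimized by
# Newton steps (Hessian = covariance of the basis under p(l)) with
# backtracking.

maxent_core <- function(m1, m2, m3, ages = hl_support_ages(),
                        tol = 1e-8, max_iter = 200L) {
  cm <- central_moments(m1, m2, m3)
  mean_age <- 60 + m1
  lo <- min(ages); hi <- max(ages)
  if (mean_age < lo - 1e-9 || mean_age > hi + 1e-9) {
    abort(sprintf("Infeasible moments: mean exit age %.4f outside [%d, %d].",
                  mean_age, lo, hi), class = "hl_infeasible_error")
  }

  if (cm$degenerate) {
    p <- numeric(length(ages))
    p[which.min(abs(ages - mean_age))] <- 1
    return(list(p = p, ages = ages, lambda = rep(NA_real_, 3),
                center = mean_age, scale = 0, converged = TRUE,
                residual = 0, iterations = 0L, degenerate = TRUE))
  }

  # exact upper bound on the variance of a distribution on [lo, hi] with
  # this mean (attained by the two-point distribution on {lo, hi})
  vmax <- (mean_age - lo) * (hi - mean_age)
  if (cm$variance > vmax * (1 + 1e-9)) {
    abort(sprintf(
      "Infeasible moments: variance %.4f exceeds the bound (mean-%d)(%d-mean) = %.4f.",
      cm$variance, lo, hi, vmax), class = "hl_infeasible_error")
  }

  sdev <- sqrt(cm$variance)
  z <- (ages - mean_age) / sdev
  FB <- rbind(z, z^2, z^3)                    # 3 x n basis
  targ <- c(0, 1, cm$skewness)

  dual <- function(l) {
    w <- drop(crossprod(FB, l))
    m <- max(w)
    log(sum(exp(w - m))) + m - sum(l * targ)
  }

  lambda <- c(0, 0, 0)
  psi <- dual(lambda)
  residual <- Inf
  iter <- 0L
  repeat {
    w <- drop(crossprod(FB, lambda))
    p <- exp(w - max(w)); p <- p / sum(p)
    mu <- drop(FB %*% p)
    g <- mu - targ
    residual <- max(abs(g))
    if (residual < tol || iter >= max_iter) break
    H <- tcrossprod(FB * rep(p, each = 3L), FB) - tcrossprod(mu)
    step <- tryCatch(-solve(H, g),
                     error = function(e) -solve(H + diag(1e-10, 3), g))
    alpha <- 1
    # Armijo backtracking; the epsilon slack keeps the final Newton steps
    # from stalling once the dual decrease falls below machine precision
    slack <- 4 * .Machine$double.eps * (1 + abs(psi))
    repeat {
      cand <- lambda + alpha * step
      psi_new <- dual(cand)
      if (psi_new <= psi + 1e-4 * alpha * sum(g * step) + slack ||
          alpha < 1e-12) break
      alpha <- alpha / 2
    }
    lambda <- lambda + alpha * step
    psi <- dual(lambda)
    iter <- iter + 1L
  }

  if (residual >= tol) {
    abort(sprintf(
      "Maximum-entropy fit did not converge in %d iterations (residual %.3e, lambda = %s).",
      iter, residual, paste(signif(lambda, 6), collapse = ", ")),
      class = "hl_maxent_error",
      residual = residual, lambda = lambda, iterations = iter)
  }
  list(p = p, ages = ages, lambda = lambda, center = mean_age, scale = sdev,
       converged = TRUE, residual = residual, iterations = iter,
       degenerate = FALSE)
}

#' Maximum-entropy exit-age distribution from three moments
#'
#' Reconstructs the discrete probability distribution of the age of health
#' loss on ages 60--90 (31 atoms) that maximizes Shannon entropy subject
#' to the first three moments of healthy years, as computed by
#' [mcwr_moments()].  A zero-variance (degenerate) moment set yields a
#' point mass at the nearest support age.
#'
#' @param moments An `hl_moments` object, or anything with elements
#'   `m1`, `m2`, `m3` (raw moments of healthy years in `[0, 30]`).
#' @param ages Support ages (default 60--90).
#' @param tol Convergence tolerance on the standardized moment residuals.
#' @param max_iter Maximum Newton iterations.
#' @return An object of class `hl_maxent` with `pmf` (tibble `age`,
#'   `phloss`, `lhealth`), `lambda`, `mode_age`, `mode_prob`,
#'   `converged`, `residual`, `iterations`.  `tidy()` returns the pmf
#'   tibble; `glance()` the convergence and mode summary.
#' @examples
#' mom <- mcwr_moments(sim_mortality_schedule(), sim_prevalence_schedule())
#' fit <- solve_maxent(mom)
#' glance(fit)
#' @export
solve_maxent <- function(moments, ages = hl_support_ages(),
                         tol = 1e-8, max_iter = 200L) {
  m <- as.list(moments)[c("m1", "m2", "m3")]
  if (anyNA(m) || any(lengths(m) != 1L)) {
    abort("`moments` must carry numeric elements m1, m2, m3.",
          class = "hl_input_error")
  }
  sol <- maxent_core(m$m1, m$m2, m$m3, ages = ages, tol = tol,
                     max_iter = max_iter)
  p <- sol$p
  lhealth <- rev(cumsum(rev(p)))
  md <- which.max(p)
  structure(
    list(pmf = tibble::tibble(age = as.integer(sol$ages), phloss = p,
                              lhealth = lhealth),
         lambda = sol$lambda, center = sol$center, scale = sol$scale,
         mode_age = as.integer(sol$ages[md]), mode_prob = p[md],
         converged = sol$converged, residual = sol$residual,
         iterations = sol$iterations, degenerate = sol$degenerate,
         moments = list(m1 = m$m1, m2 = m$m2, m3 = m$m3)),
    class = "hl_maxent"
  )
}

#' @export
print.hl_maxent <- function(x, ...) {
  cat(sprintf("<hl_maxent> exit-age distribution on %d--%d\n",
              min(x$pmf$age), max(x$pmf$age)))
  cat(sprintf("  mode at age %d (p = %.4f); %s after %d iteration(s), residual %.1e\n",
              x$mode_age, x$mode_prob,
              if (x$degenerate) "degenerate point mass" else "converged",
              x$iterations, x$residual))
  invisible(x)
}

#' @describeIn solve_maxent The fitted pmf as a tibble (`age`, `phloss`,
#'   `lhealth`).
#' @param x An `hl_maxent` object.
#' @param ... Unused.
#' @export
tidy.hl_maxent <- function(x, ...) x$pmf

#' @describeIn solve_maxent One-row convergence and mode summary.
#' @export
glance.hl_maxent <- function(x, ...) {
  tibble::tibble(converged = x$converged, iterations = x$iterations,
                 residual = x$residual, degenerate = x$degenerate,
                 mode_age = x$mode_age, mode_prob = x$mode_prob)
}

#' Survival curve of the healthy state from a pmf
#'
#' \eqn{lhealth_x = \sum_{y \ge x} phloss_y}: the probability of still
#' being healthy at exact age \eqn{x}, with \eqn{lhealth_{60} = 1} and
#' \eqn{lhealth_{91} = 0}.
#'
#' @param pmf Tibble with `age` (60--90) and `phloss` (or `p`).
#' @return A tibble with `age` (60--91) and `lhealth`.
#' @export
health_survival <- function(pmf) {
  p <- check_pmf(pmf)
  ages <- hl_support_ages()
  tibble::tibble(age = c(ages, 91L),
                 lhealth = c(rev(cumsum(rev(p))), 0))
}

#' Mode of an exit-age distribution
#'
#' @inheritParams health_survival
#' @return A one-row tibble with `mode_age` (ties broken to the smallest
#'   age) and `mode_prob`.
#' @export
dist_mode <- function(pmf) {
  p <- check_pmf(pmf)
  i <- which.max(p)
  tibble::tibble(mode_age = hl_support_ages()[i], mode_prob = p[i])
}

#' Tail diagnostic against a reference distribution
#'
#' Compares a fitted exit-age distribution with a reference pmf on the
#' same support (typically the Monte-Carlo oracle of
#' [simulate_healthy_years()]), reporting per-age signed differences
#' (fitted − reference) and the total variation distance.  Purely
#' diagnostic: three-moment maximum entropy is known to thin the old-age
#' tail relative to the generating model, shifting mass to younger ages.
#'
#' @param pmf Fitted pmf tibble (`age`, `phloss` or `p`).
#' @param reference Reference pmf tibble on the same support.
#' @return An object of class `hl_tail_diag`; `tidy()` gives the per-age
#'   table, `glance()` the total variation distance.
#' @export
tail_diagnostic <- function(pmf, reference) {
  p <- check_pmf(pmf)
  q <- check_pmf(reference, arg = "reference")
  by_age <- tibble::tibble(age = hl_support_ages(), fitted = p,
                           reference = q, diff = p - q)
  structure(list(by_age = by_age, tv = sum(abs(p - q)) / 2),
            class = "hl_tail_diag")
}

#' @export
print.hl_tail_diag <- function(x, ...) {
  cat(sprintf("<hl_tail_diag> total variation distance %.4f\n", x$tv))
  worst <- x$by_age[order(-abs(x$by_age$diff)), ][1:3, ]
  cat("  largest deviations (fitted - reference):\n")
  for (i in 1:3) {
    cat(sprintf("    age %d: %+.4f\n", worst$age[i], worst$diff[i]))
  }
  invisible(x)
}

#' @describeIn tail_diagnostic Per-age differences.
#' @param x An `hl_tail_diag` object.
#' @param ... Unused.
#' @export
tidy.hl_tail_diag <- function(x, ...) x$by_age

#' @describeIn tail_diagnostic Total variation distance.
#' @export
glance.hl_tail_diag <- function(x, ...) tibble::tibble(tv = x$tv)
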