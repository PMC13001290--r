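# Survey-weighted bootstrap of the prevalence inputs, propagated through
# moments -> maximum entropy -> comparison, with percentile intervals.

#' Percentile confidence interval
#'
#' Empirical percentile interval with linear interpolation between order
#' statistics (R's `quantile()` type 7, the documented rule here).  For
#' integer-valued quantities (e.g. the mode age) each endpoint is snapped
#' to the nearest value attained among the replicates.
#'
#' @param values Numeric replicate values (at least one; empty is an
#'   error).
#' @param level Confidence level in percent (default 95).
#' @param integer Snap endpoints to attained values?
#' @return A one-row tibble with `lower` and `upper`.
#' @examples
#' percentile_ci(1:100)  # 3.475, 97.525
#' @export
percentile_ci <- function(values, level = 95, integer = FALSE) {
  if (length(values) == 0) {
    abort("`values` is empty.", class = "hl_input_error")
  }
  check_number(level, "level", lower = .Machine$double.eps, upper = 100 - 1e-12)
  alpha <- (1 - level / 100) / 2
  qs <- quantile(values, c(alpha, 1 - alpha), type = 7, names = FALSE)
  if (integer) {
    qs <- vapply(qs, function(q) values[which.min(abs(values - q))], numeric(1))
  }
  tibble::tibble(lower = qs[1], upper = qs[2])
}

#' Weighted bootstrap of age-specific prevalence
#'
#' For each replicate and each (grouping × age) stratum of size \eqn{n},
#' draws \eqn{n} records with replacement and recomputes the healthy
#' prevalence.  Two resampling estimators are provided, because "weighted
#' sampling with replacement" admits both readings:
#' * `"selection"` (default): selection probability proportional to the
#'   calibrated weight, replicate prevalence = unweighted mean of the
#'   resampled indicators;
#' * `"reweight"`: uniform resampling, replicate prevalence = weighted
#'   mean of the resampled records (the classical bootstrap of the
#'   weighted estimator; use this when frequentist coverage of the
#'   intervals matters).
#'
#' Replicate `r` uses seed `seed + r`, so any single replicate is
#' reproducible independently of `n_reps`.
#'
#' @param data Microdata tibble with `age`, `weight` and a logical
#'   `healthy` column ([derive_health_indicator()]).
#' @param by Grouping columns defining strata together with `age`.
#' @param n_reps Number of bootstrap replicates (default 5000; scale down
#'   for exploratory runs).
#' @param seed Base integer seed.
#' @param scheme `"selection"` or `"reweight"` (see above).
#' @param ages Required age grid.
#' @return A tibble with `rep`, the `by` columns, `age` and `hx`; one row
#'   per replicate and stratum.
#' @export
bootstrap_prevalence <- function(data, by = c("wave", "sex"), n_reps = 5000,
                                 seed = 1L, scheme = c("selection", "reweight"),
                                 ages = 60:89) {
  scheme <- match.arg(scheme)
  if (n_reps < 2) abort("`n_reps` must be >= 2.", class = "hl_input_error")
  need <- c(by, "age", "weight", "healthy")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    abort(sprintf("`data` lacks column(s): %s.", paste(miss, collapse = ", ")),
          class = "hl_input_error")
  }
  data <- data[data$age < 90, , drop = FALSE]
  key <- do.call(paste, c(data[c(by, "age")], sep = "\r"))
  strata <- split(data.frame(y = as.numeric(data$healthy), w = data$weight),
                  key)
  sizes <- vapply(strata, nrow, integer(1))
  if (any(sizes == 1L)) {
    warn(sprintf("%d stratum(s) of size 1: their bootstrap CIs are degenerate.",
                 sum(sizes == 1L)))
  }
  # stratum key columns, in a stable order matching `strata`
  key_tbl <- dplyr::distinct(data[c(by, "age")])
  key_tbl <- key_tbl[match(names(strata),
                           do.call(paste, c(key_tbl, sep = "\r"))), ]
  n_strata <- length(strata)

  hx <- matrix(NA_real_, n_reps, n_strata)
  for (r in seq_len(n_reps)) {
    with_seed(seed + r, {
      for (j in seq_len(n_strata)) {
        st <- strata[[j]]
        n <- nrow(st)
        if (scheme == "selection") {
          idx <- sample.int(n, n, replace = TRUE, prob = st$w)
          hx[r, j] <- mean(st$y[idx])
        } else {
          idx <- sample.int(n, n, replace = TRUE)
          hx[r, j] <- sum(st$w[idx] * st$y[idx]) / sum(st$w[idx])
        }
      }
    })
  }
  out <- key_tbl[rep(seq_len(n_strata), times = n_reps), , drop = FALSE]
  out$rep <- rep(seq_len(n_reps), each = n_strata)
  out$hx <- as.vector(t(hx))
  tibble::as_tibble(out[, c("rep", by, "age", "hx")]) |>
    dplyr::arrange(.data$rep, dplyr::across(dplyr::all_of(c(by, "age"))))
}

#' Propagate bootstrap prevalence replicates through the pipeline
#'
#' Re-runs the rewards-moment computation and (optionally) the
#' maximum-entropy fit for every replicate prevalence schedule, holding
#' the mortality schedule fixed (only the prevalence carries sampling
#' error).  When the replicates contain exactly two groups and
#' `compare = TRUE`, the outsurvival statistic and Hellinger distance are
#' computed per replicate between them.
#'
#' @param replicates Output of [bootstrap_prevalence()].
#' @param mortality Mortality tibble with `age`, `qx`, and optionally the
#'   grouping columns (a single schedule is recycled to all groups).
#' @param by Grouping columns present in `replicates` (default: all
#'   non-`rep`/`age`/`hx` columns).
#' @param convention,condition_on_healthy_at_60 Passed to the moment
#'   recursion.
#' @param maxent Fit the exit-age distribution per replicate?
#' @param compare Compute `phi`/`hd` between the two groups per replicate?
#'   Requires `maxent = TRUE` and exactly two groups; group 1 is the first
#'   in sort order (sort `by` values so that population 1 comes first, or
#'   pass a factor).
#' @param max_drop_frac Abort if more than this fraction of replicates
#'   fails the maximum-entropy fit (default 0.01).
#' @return An object of class `hl_bootstrap` holding per-replicate tibbles
#'   `moments` (and `pmf`, `mode`, `comparison` when enabled) plus the
#'   dropped-replicate count.  `tidy()` returns percentile CIs for every
#'   scalar quantity.
#' @export
bootstrap_pipeline <- function(replicates, mortality, by = NULL,
                               convention = c("occupancy", "survived-year"),
                               condition_on_healthy_at_60 = TRUE,
                               maxent = TRUE, compare = FALSE,
                               max_drop_frac = 0.01) {
  convention <- match.arg(convention)
  by <- by %||% setdiff(names(replicates), c("rep", "age", "hx"))
  ages <- hl_transient_ages()

  groups <- dplyr::distinct(replicates[by]) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(by)))
  glab <- function(tbl) {
    if (length(by) == 0) rep("all", nrow(tbl)) else do.call(paste, c(tbl[by], sep = "/"))
  }
  group_labels <- glab(groups)
  if (compare && (!maxent || nrow(groups) != 2L)) {
    abort("`compare = TRUE` needs `maxent = TRUE` and exactly two groups.",
          class = "hl_input_error")
  }

  # per-group fixed qx vector
  qx_for <- function(i) {
    m <- mortality
    for (col in intersect(by, names(m))) m <- m[m[[col]] == groups[[col]][i], ]
    check_schedule(m, "qx", arg = "mortality")
  }
  qx_list <- lapply(seq_len(nrow(groups)), qx_for)

  rep_lab <- glab(replicates)
  by_rep <- split(data.frame(lab = rep_lab, age = replicates$age,
                             hx = replicates$hx, stringsAsFactors = FALSE),
                  replicates$rep)
  rep_ids <- as.integer(names(by_rep))
  moments_rows <- list()
  pmf_rows <- list()
  cmp_rows <- list()
  dropped <- 0L

  for (r in seq_along(by_rep)) {
    sub <- by_rep[[r]]
    mom_local <- pmf_local <- vector("list", nrow(groups))
    fits <- vector("list", nrow(groups))
    failed <- FALSE
    for (i in seq_len(nrow(groups))) {
      g <- sub[sub$lab == group_labels[i], ]
      hx <- g$hx[match(ages, g$age)]
      mm <- mcwr_core(qx_list[[i]], hx, convention, condition_on_healthy_at_60)
      cm <- central_moments(mm[["m1"]], mm[["m2"]], mm[["m3"]])
      mom_local[[i]] <- dplyr::bind_cols(
        groups[i, , drop = FALSE],
        tibble::tibble(rep = rep_ids[r], m1 = mm[["m1"]], m2 = mm[["m2"]],
                       m3 = mm[["m3"]], hle = 60 + mm[["m1"]],
                       sdhl = sqrt(cm$variance), skewness = cm$skewness))
      if (maxent) {
        fit <- tryCatch(
          maxent_core(mm[["m1"]], mm[["m2"]], mm[["m3"]]),
          hl_maxent_error = function(e) NULL,
          hl_infeasible_error = function(e) NULL)
        if (is.null(fit)) { failed <- TRUE; break }
        fits[[i]] <- fit
        md <- which.max(fit$p)
        pmf_local[[i]] <- dplyr::bind_cols(
          groups[i, , drop = FALSE],
          tibble::tibble(rep = rep_ids[r], age = as.integer(fit$ages),
                         phloss = fit$p, mode_age = as.integer(fit$ages[md]),
                         mode_prob = fit$p[md]))
      }
    }
    if (failed) { dropped <- dropped + 1L; next }
    moments_rows[[length(moments_rows) + 1L]] <- dplyr::bind_rows(mom_local)
    if (maxent) pmf_rows[[length(pmf_rows) + 1L]] <- dplyr::bind_rows(pmf_local)
    if (compare) {
      p1 <- fits[[1]]$p; p2 <- fits[[2]]$p
      surv1_next <- c(rev(cumsum(rev(p1)))[-1], 0)
      phi <- sum(p2 * surv1_next) + sum(p1 * p2) / 2
      bc <- sum(sqrt(p1) * sqrt(p2))
      hd <- sqrt(max(2 * sum((sqrt(p1) - sqrt(p2))^2), 0))
      cmp_rows[[length(cmp_rows) + 1L]] <-
        tibble::tibble(rep = rep_ids[r], phi = phi, hd = hd, bc = bc)
    }
  }

  if (dropped > max_drop_frac * length(rep_ids)) {
    abort(sprintf("%d of %d bootstrap replicates failed the maximum-entropy fit (> %.0f%%).",
                  dropped, length(rep_ids), 100 * max_drop_frac),
          class = "hl_maxent_error")
  }
  structure(
    list(moments = dplyr::bind_rows(moments_rows),
         pmf = if (maxent) dplyr::bind_rows(pmf_rows),
         comparison = if (compare) dplyr::bind_rows(cmp_rows),
         by = by, dropped = dropped, n_reps = length(rep_ids),
         convention = convention),
    class = "hl_bootstrap")
}

#' @export
print.hl_bootstrap <- function(x, ...) {
  cat(sprintf("<hl_bootstrap> %d replicate(s), %d dropped\n", x$n_reps, x$dropped))
  print(tidy(x), n = 20)
  invisible(x)
}

#' @describeIn bootstrap_pipeline Percentile CIs (2.5th/97.5th at the
#'   default level) for HLE, SDHL, skewness, per-age `phloss`, mode age
#'   and probability, and `phi`/`hd` when computed.
#' @param x An `hl_bootstrap` object.
#' @param level Confidence level in percent.
#' @param ... Unused.
#' @export
tidy.hl_bootstrap <- function(x, level = 95, ...) {
  by <- x$by
  ci_of <- function(tbl, col, integer = FALSE, age = FALSE) {
    grp <- c(by, if (age) "age")
    # skewness is undefined (NA) for degenerate replicates; interval over
    # the defined ones, all-NA groups stay NA
    ci_safe <- function(v) {
      v <- v[!is.na(v)]
      if (length(v) == 0) return(tibble::tibble(lower = NA_real_, upper = NA_real_))
      percentile_ci(v, level = level, integer = integer)
    }
    tbl |>
      dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
      dplyr::summarise(
        quantity = col,
        replicate_mean = mean(.data[[col]], na.rm = TRUE),
        ci_safe(.data[[col]]),
        .groups = "drop")
  }
  rows <- list(
    ci_of(x$moments, "hle"), ci_of(x$moments, "sdhl"),
    ci_of(x$moments, "skewness"))
  if (!is.null(x$pmf)) {
    rows <- c(rows, list(
      ci_of(x$pmf, "phloss", age = TRUE),
      ci_of(dplyr::distinct(x$pmf, dplyr::across(dplyr::all_of(c(x$by, "rep"))),
                            .data$mode_age, .data$mode_prob),
            "mode_age", integer = TRUE),
      ci_of(dplyr::distinct(x$pmf, dplyr::across(dplyr::all_of(c(x$by, "rep"))),
                            .data$mode_age, .data$mode_prob),
            "mode_prob")))
  }
  if (!is.null(x$comparison)) {
    cmp <- x$comparison
    rows <- c(rows, list(
      tibble::tibble(quantity = "phi", replicate_mean = mean(cmp$phi),
                     percentile_ci(cmp$phi, level = level)),
      tibble::tibble(quantity = "hd", replicate_mean = mean(cmp$hd),
                     percentile_ci(cmp$hd, level = level))))
  }
  dplyr::bind_rows(rows)
}
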