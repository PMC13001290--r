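# End-to-end orchestration: simulate/ingest -> prepare -> moments ->
# maximum entropy -> compare -> (optional) bootstrap, with tidy CSV
# outputs and a JSON run manifest.

#' Run the full healthy-longevity pipeline
#'
#' Executes every stage on survey microdata (supplied or synthetic) and a
#' mortality schedule (supplied or synthetic Gompertz), for one or more
#' health measures.  Writes `moments.csv`, `pmf.csv`, `comparisons.csv`
#' (and `ci.csv` when bootstrapping) plus `manifest.json` into `out_dir`
#' when it is given; runs are idempotent given the seed.
#'
#' @param microdata Microdata tibble or CSV path; `NULL` (default)
#'   simulates a survey with [sim_survey()] using `n_per_stratum` and
#'   `seed`.
#' @param mortality Mortality tibble with columns `sex`, `age`, `qx` (or a
#'   single schedule applied to both sexes); `NULL` uses
#'   [sim_default_mortality()].
#' @param measures List of [health_measure()] objects (default: the full
#'   [hl_measures()] set).
#' @param out_dir Output directory, created if needed; `NULL` writes
#'   nothing.
#' @param n_per_stratum Synthetic stratum size when simulating.
#' @param convention,condition_on_healthy_at_60 Reward convention.
#' @param bootstrap Number of bootstrap replicates; 0 (default) disables
#'   the uncertainty stage.
#' @param bootstrap_scheme Resampling estimator, see
#'   [bootstrap_prevalence()].
#' @param seed Integer seed governing simulation and bootstrap.
#' @return A list of class `hl_run` with tibbles `moments`, `pmf`,
#'   `comparisons`, optional `ci`, and the `manifest` list.
#' @examples
#' \donttest{
#' run <- run_pipeline(n_per_stratum = 20,
#'                     measures = hl_measures()["chronic_free"], seed = 1)
#' run$comparisons
#' }
#' @export
run_pipeline <- function(microdata = NULL, mortality = NULL,
                         measures = hl_measures(), out_dir = NULL,
                         n_per_stratum = 100,
                         convention = c("occupancy", "survived-year"),
                         condition_on_healthy_at_60 = TRUE,
                         bootstrap = 0, bootstrap_scheme = "selection",
                         seed = 1L) {
  convention <- match.arg(convention)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            class = "hl_pipeline_error", parent = e)
    })
  }

  md <- stage("ingest", {
    if (is.null(microdata)) {
      sim_survey(n_per_stratum = n_per_stratum, seed = seed)
    } else if (is.character(microdata)) {
      readr::read_csv(microdata, show_col_types = FALSE, progress = FALSE)
    } else {
      tibble::as_tibble(microdata)
    }
  })
  mort <- stage("ingest", {
    m <- mortality %||% sim_default_mortality()
    if (!"sex" %in% names(m)) {
      m <- dplyr::bind_rows(lapply(unique(md$sex), \(s) dplyr::mutate(m, sex = s)))
    }
    m
  })
  if (is.null(measures) || length(measures) == 0) {
    abort("`measures` must be a non-empty list of health_measure objects.",
          class = "hl_input_error")
  }
  if (is.null(names(measures))) {
    names(measures) <- vapply(measures, `[[`, "", "name")
  }

  waves <- sort(unique(md$wave))
  sexes <- sort(unique(md$sex))
  moments_out <- pmf_out <- cmp_out <- ci_out <- list()

  for (mname in names(measures)) {
    meas <- measures[[mname]]
    flagged <- stage("prepare",
                     suppressMessages(derive_health_indicator(md, meas)))
    prev <- stage("prepare", weighted_prevalence(flagged, by = c("wave", "sex")))

    fits <- list()
    for (w in waves) for (s in sexes) {
      p_ws <- dplyr::filter(prev, .data$wave == w, .data$sex == s)
      m_s <- dplyr::filter(mort, .data$sex == s)
      mom <- stage("moments",
                   mcwr_moments(m_s, p_ws, convention = convention,
                                condition_on_healthy_at_60 = condition_on_healthy_at_60))
      fit <- stage("maxent", solve_maxent(mom))
      key <- tibble::tibble(measure = mname, wave = w, sex = s)
      moments_out[[length(moments_out) + 1L]] <- dplyr::bind_cols(key, tidy(mom))
      pmf_out[[length(pmf_out) + 1L]] <-
        dplyr::bind_cols(key[rep(1, 31), ], tidy(fit))
      fits[[paste(w, s)]] <- fit
    }

    if (length(sexes) == 2L) {
      for (w in waves) {
        # population 1 = male: phi reads "male outsurvives female in health"
        cmp <- stage("compare",
                     compare_distributions(fits[[paste(w, "male")]],
                                           fits[[paste(w, "female")]]))
        cmp_out[[length(cmp_out) + 1L]] <-
          dplyr::bind_cols(tibble::tibble(measure = mname, wave = w), cmp)
      }
    }

    if (bootstrap > 0) {
      reps <- stage("bootstrap",
                    bootstrap_prevalence(flagged, by = c("wave", "sex"),
                                         n_reps = bootstrap, seed = seed,
                                         scheme = bootstrap_scheme))
      for (w in waves) {
        bt <- stage("bootstrap", bootstrap_pipeline(
          dplyr::filter(reps, .data$wave == w), mort, by = "sex",
          convention = convention,
          condition_on_healthy_at_60 = condition_on_healthy_at_60,
          maxent = TRUE, compare = length(sexes) == 2L))
        ci_out[[length(ci_out) + 1L]] <- dplyr::bind_cols(
          tibble::tibble(measure = mname, wave = w), tidy(bt))
      }
    }
  }

  result <- structure(
    list(moments = dplyr::bind_rows(moments_out),
         pmf = dplyr::bind_rows(pmf_out),
         comparisons = dplyr::bind_rows(cmp_out),
         ci = if (bootstrap > 0) dplyr::bind_rows(ci_out),
         manifest = list(
           package = "hldist",
           version = as.character(utils::packageVersion("hldist")),
           seed = seed, convention = convention,
           condition_on_healthy_at_60 = condition_on_healthy_at_60,
           measures = names(measures), waves = waves, sexes = sexes,
           synthetic_microdata = is.null(microdata),
           n_per_stratum = if (is.null(microdata)) n_per_stratum,
           bootstrap = bootstrap, bootstrap_scheme = bootstrap_scheme,
           maxent_tol = 1e-8)),
    class = "hl_run")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(result$moments, file.path(out_dir, "moments.csv"))
    readr::write_csv(result$pmf, file.path(out_dir, "pmf.csv"))
    readr::write_csv(result$comparisons, file.path(out_dir, "comparisons.csv"))
    if (!is.null(result$ci)) {
      readr::write_csv(result$ci, file.path(out_dir, "ci.csv"))
    }
    jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  result
}

#' @export
print.hl_run <- function(x, ...) {
  cat(sprintf("<hl_run> %d measure(s) x %d wave(s) x %d sex(es), seed %s\n",
              length(x$manifest$measures), length(x$manifest$waves),
              length(x$manifest$sexes), x$manifest$seed))
  cat("moments:\n"); print(x$moments, n = 8)
  if (nrow(x$comparisons) > 0) { cat("comparisons:\n"); print(x$comparisons, n = 8) }
  invisible(x)
}
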