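# Health-measure definitions and survey preparation: per-record healthy
# indicators and age-specific weighted prevalence.

#' Define a health measure
#'
#' Three modes mirror the standard survey-based definitions of being
#' healthy at interview:
#' * `"all-free"`: healthy iff free of every listed condition;
#' * `"at-most-one"`: healthy iff no condition or exactly one;
#' * `"cognitive-threshold"`: healthy iff every available cognitive test
#'   score lies above (reference mean − `threshold_sd` × reference SD) and
#'   there is no dementia/Alzheimer's diagnosis.  The reference statistics
#'   are computed over all person-wave observations pooled (optionally
#'   within education level when `education_adjusted = TRUE`).
#'
#' @param mode One of `"all-free"`, `"at-most-one"`, `"cognitive-threshold"`.
#' @param conditions Character vector of condition column names (required
#'   for the first two modes).
#' @param threshold_sd Positive threshold in SD units (default 1.5).
#' @param education_adjusted Compute cognitive reference statistics within
#'   education strata?
#' @param name Optional label carried into outputs.
#' @return An object of class `hl_measure`.
#' @seealso [hl_measures()] for a ready-made set.
#' @export
health_measure <- function(mode = c("all-free", "at-most-one", "cognitive-threshold"),
                           conditions = NULL, threshold_sd = 1.5,
                           education_adjusted = FALSE, name = NULL) {
  mode <- match.arg(mode)
  if (mode != "cognitive-threshold" && (is.null(conditions) || length(conditions) == 0)) {
    abort("`conditions` must be a non-empty character vector for this mode.",
          class = "hl_input_error")
  }
  check_number(threshold_sd, "threshold_sd", lower = .Machine$double.eps)
  structure(
    list(mode = mode, conditions = conditions, threshold_sd = threshold_sd,
         education_adjusted = isTRUE(education_adjusted),
         name = name %||% mode),
    class = "hl_measure"
  )
}

#' @export
print.hl_measure <- function(x, ...) {
  cat(sprintf("<hl_measure> %s (%s)\n", x$name, x$mode))
  if (!is.null(x$conditions)) {
    cat("  conditions:", paste(x$conditions, collapse = ", "), "\n")
  }
  if (x$mode == "cognitive-threshold") {
    cat(sprintf("  threshold: mean - %.2f SD%s\n", x$threshold_sd,
                if (x$education_adjusted) " (within education level)" else ""))
  }
  invisible(x)
}

#' Standard set of health measures
#'
#' The seven prevalence-based measures used throughout: free from major
#' chronic conditions; no more than one chronic condition; free from any
#' cardiovascular disease; free from cardiovascular conditions/risk
#' factors; free from arthritis or rheumatism; good cognitive health
#' (general-population reference); good cognitive health
#' (education-adjusted reference).
#'
#' @return A named list of [health_measure()] objects.
#' @export
hl_measures <- function() {
  chronic <- c("hypertension", "high_cholesterol", "heart_problems", "stroke",
               "diabetes", "lung_disease", "arthritis", "parkinsons",
               "alzheimers")
  list(
    chronic_free   = health_measure("all-free", chronic, name = "chronic_free"),
    chronic_max1   = health_measure("at-most-one", chronic, name = "chronic_max1"),
    cvd_free       = health_measure("all-free", c("heart_problems", "stroke"),
                                    name = "cvd_free"),
    cvd_risk_free  = health_measure("all-free",
                                    c("hypertension", "high_cholesterol",
                                      "heart_problems", "stroke"),
                                    name = "cvd_risk_free"),
    arthritis_free = health_measure("all-free", "arthritis",
                                    name = "arthritis_free"),
    cognition      = health_measure("cognitive-threshold", name = "cognition"),
    cognition_edu  = health_measure("cognitive-threshold",
                                    education_adjusted = TRUE,
                                    name = "cognition_edu")
  )
}

cognitive_tests <- function() c("cog_orientation", "cog_fluency", "cog_memory")

#' Derive the per-record healthy indicator
#'
#' Adds a logical `healthy` column according to a [health_measure()].
#' Records that cannot be classified (missing condition indicators under
#' the default policy, or all cognitive scores missing) are dropped, and
#' the dropped count is reported via a message.
#'
#' @param data Survey microdata tibble (one row per person-wave).
#' @param measure An [health_measure()] object.
#' @param cognition_reference `"pooled"` (default): cognitive reference
#'   mean/SD per test over all person-wave observations in `data`, both
#'   sexes and all waves together; `"by-wave"` restricts the reference to
#'   each wave.
#' @param missing_conditions `"drop"` (default) removes records with a
#'   missing indicator among the measure's conditions; `"absent"` treats
#'   missing as condition-free.
#' @return `data` (minus dropped records) with a `healthy` logical column.
#' @export
derive_health_indicator <- function(data, measure,
                                    cognition_reference = c("pooled", "by-wave"),
                                    missing_conditions = c("drop", "absent")) {
  if (!inherits(measure, "hl_measure")) {
    abort("`measure` must be created with health_measure().",
          class = "hl_input_error")
  }
  cognition_reference <- match.arg(cognition_reference)
  missing_conditions <- match.arg(missing_conditions)
  data <- tibble::as_tibble(data)

  if (measure$mode %in% c("all-free", "at-most-one")) {
    miss_cols <- setdiff(measure$conditions, names(data))
    if (length(miss_cols) > 0) {
      abort(sprintf("Microdata lacks condition column(s): %s.",
                    paste(miss_cols, collapse = ", ")), class = "hl_input_error")
    }
    cond <- as.matrix(data[measure$conditions])
    storage.mode(cond) <- "logical"
    any_na <- rowSums(is.na(cond)) > 0
    if (missing_conditions == "absent") {
      cond[is.na(cond)] <- FALSE
      any_na[] <- FALSE
    }
    n_cond <- rowSums(cond)
    healthy <- if (measure$mode == "all-free") n_cond == 0 else n_cond <= 1
    drop <- any_na
  } else {
    tests <- cognitive_tests()
    need <- c(tests, "dementia_dx",
              if (measure$education_adjusted) "education")
    miss_cols <- setdiff(need, names(data))
    if (length(miss_cols) > 0) {
      abort(sprintf("Microdata lacks column(s): %s.",
                    paste(miss_cols, collapse = ", ")), class = "hl_input_error")
    }
    group_cols <- c(if (cognition_reference == "by-wave") "wave",
                    if (measure$education_adjusted) "education")
    key <- if (length(group_cols) == 0) {
      rep("all", nrow(data))
    } else {
      do.call(paste, c(data[group_cols], sep = "\r"))
    }
    pass <- matrix(NA, nrow(data), length(tests))
    for (j in seq_along(tests)) {
      score <- data[[tests[j]]]
      mu <- tapply(score, key, mean, na.rm = TRUE)[key]
      sdev <- tapply(score, key, sd, na.rm = TRUE)[key]
      pass[, j] <- score > (mu - measure$threshold_sd * sdev)
    }
    all_missing <- rowSums(!is.na(pass)) == 0
    # a missing individual test is skipped; any observed failure => unhealthy
    fails <- rowSums(!pass, na.rm = TRUE) > 0
    healthy <- !fails & !as.logical(data$dementia_dx)
    drop <- all_missing | is.na(data$dementia_dx)
  }

  if (any(drop)) {
    rlang::inform(sprintf("derive_health_indicator: dropped %d unclassifiable record(s) for measure '%s'.",
                          sum(drop), measure$name))
  }
  out <- data[!drop, , drop = FALSE]
  out$healthy <- healthy[!drop]
  out
}

#' Weighted age-specific healthy prevalence
#'
#' Estimates \eqn{h_x}, the probability of being healthy at age \eqn{x},
#' as the calibrated-weight share of healthy respondents within each
#' (grouping × age) stratum: \eqn{h_x = \sum w_i y_i / \sum w_i}.
#' Ages 90 and over are collapsed into an open-ended group and excluded
#' from the schedule (the model uses ages 60--89 only); ages below 60 are
#' an error.
#'
#' @param data Microdata tibble with a `healthy` column (see
#'   [derive_health_indicator()]), `age` and `weight`.
#' @param by Character vector of grouping columns (default
#'   `c("wave", "sex")`).
#' @param ages Required age grid (default 60--89); any missing
#'   (group, age) stratum is an error.
#' @return A tibble with the `by` columns, `age`, `hx`, unweighted size
#'   `n` and Kish effective size `n_eff`.
#' @export
weighted_prevalence <- function(data, by = c("wave", "sex"), ages = 60:89) {
  need <- c(by, "age", "weight", "healthy")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    abort(sprintf("`data` lacks column(s): %s.", paste(miss, collapse = ", ")),
          class = "hl_input_error")
  }
  if (any(data$age < 60)) {
    abort("Ages below 60 present; restrict the analysis to ages 60+.",
          class = "hl_input_error")
  }
  if (any(data$weight <= 0)) {
    abort("Weights must be strictly positive.", class = "hl_input_error")
  }
  data <- data[data$age < 90, , drop = FALSE]   # 90+ collapsed & unused

  out <- data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "age")))) |>
    dplyr::summarise(
      hx = sum(.data$weight * .data$healthy) / sum(.data$weight),
      n = dplyr::n(),
      n_eff = sum(.data$weight)^2 / sum(.data$weight^2),
      .groups = "drop"
    )

  full <- tidyr::expand_grid(
    dplyr::distinct(dplyr::select(out, dplyr::all_of(by))),
    age = as.integer(ages)
  )
  missing_strata <- dplyr::anti_join(full, out, by = c(by, "age"))
  if (nrow(missing_strata) > 0) {
    lab <- do.call(paste, c(missing_strata, sep = "/"))
    abort(sprintf("Empty stratum(s): %s.",
                  paste(utils::head(lab, 10), collapse = ", ")),
          class = "hl_input_error")
  }
  dplyr::arrange(out, dplyr::across(dplyr::all_of(c(by, "age"))))
}
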