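# Synthetic schedules and survey microdata.
#
# These generators stand in for restricted survey (health prevalence) and
# life-table (mortality) sources: they produce inputs with the statistical
# structure the downstream model assumes -- age-increasing chronic-condition
# prevalence, Gompertz-type mortality, positive heterogeneous calibrated
# weights -- without claiming calibration to any real population.

# Evaluate RNG-dependent code under a local seed, restoring the caller's
# stream afterwards so package functions never clobber the session RNG.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  )
  set.seed(seed)
  force(code)
}

#' Synthetic Gompertz mortality schedule
#'
#' Annual death probabilities from a Gompertz hazard anchored at age 60:
#' the hazard at age \eqn{x} is \eqn{a\,e^{b(x-60)}} and the annual
#' probability of death is \eqn{q_x = 1 - \exp\{-a e^{b(x-60)}\}}, which
#' stays below 1 for any parameter values.
#'
#' @param ages Integer ages, within 60--89.
#' @param a Baseline hazard at age 60 (per year, > 0).
#' @param b Log-hazard slope (per year, >= 0).
#' @return A tibble with columns `age` and `qx`.
#' @examples
#' sim_mortality_schedule(a = 0.01, b = 0.09)
#' @export
sim_mortality_schedule <- function(ages = 60:89, a = 0.010, b = 0.095) {
  if (!is.numeric(a) || length(a) != 1L || is.na(a) || a <= 0) {
    abort("`a` (baseline hazard) must be a single positive number.",
          class = "hl_input_error")
  }
  check_number(b, "b", lower = 0)
  stopifnot(all(ages >= 60), all(ages <= 89))
  # clamp below 1 so extreme hazards keep q_x in [0, 1) after rounding
  tibble::tibble(age = as.integer(ages),
                 qx = pmin(1 - exp(-a * exp(b * (ages - 60))), 1 - 1e-12))
}

#' Synthetic healthy-prevalence curve
#'
#' A declining logistic probability of being healthy at each age:
#' \eqn{h_x = \mathrm{floor} + (1-\mathrm{floor}) / (1 + e^{k(x - x_0)})}.
#'
#' @param ages Integer ages, within 60--89.
#' @param x0 Logistic midpoint age.
#' @param k Steepness (per year, >= 0); `k = 0` gives a flat curve.
#' @param floor Asymptotic minimum healthy fraction, in `[0, 1)`.
#' @return A tibble with columns `age` and `hx`.
#' @examples
#' sim_prevalence_schedule(x0 = 75, k = 0.15)
#' @export
sim_prevalence_schedule <- function(ages = 60:89, x0 = 75, k = 0.15,
                                    floor = 0.05) {
  if (!is.numeric(floor) || length(floor) != 1L || is.na(floor) ||
      floor < 0 || floor >= 1) {
    abort("`floor` must be a single number in [0, 1).", class = "hl_input_error")
  }
  check_number(k, "k", lower = 0)
  check_number(x0, "x0")
  stopifnot(all(ages >= 60), all(ages <= 89))
  tibble::tibble(age = as.integer(ages),
                 hx = floor + (1 - floor) / (1 + exp(k * (ages - x0))))
}

#' Default synthetic mortality schedules by sex
#'
#' Gompertz parameters loosely typical of recent European period mortality
#' above age 60: male baseline hazard 0.010 with slope 0.095, female
#' baseline 0.0055 with slope 0.100 (female mortality lower at every age).
#'
#' @param ages Integer ages, within 60--89.
#' @return A tibble with columns `sex`, `age`, `qx`.
#' @export
sim_default_mortality <- function(ages = 60:89) {
  dplyr::bind_rows(
    dplyr::mutate(sim_mortality_schedule(ages, a = 0.0100, b = 0.095),
                  sex = "male", .before = 1),
    dplyr::mutate(sim_mortality_schedule(ages, a = 0.0055, b = 0.100),
                  sex = "female", .before = 1)
  )
}

#' Default condition-free prevalence curves
#'
#' One declining logistic curve per chronic condition and sex, giving the
#' probability of being *free* of that condition at each age.  Midpoints,
#' slopes and floors are chosen to mimic broad age patterns of European
#' survey prevalence (hypertension and high cholesterol common and early;
#' stroke and Parkinson's rare; arthritis more common in women, lung
#' disease and diabetes in men).  These are plausibility defaults, not
#' estimates.
#'
#' @return A tibble with columns `condition`, `sex`, `x0`, `k`, `floor`.
#' @export
sim_condition_curves <- function() {
  base <- tibble::tribble(
    ~condition,         ~x0,  ~k,   ~floor,
    "hypertension",      63,  0.08, 0.25,
    "high_cholesterol",  65,  0.07, 0.35,
    "heart_problems",    76,  0.09, 0.45,
    "stroke",            84,  0.10, 0.80,
    "diabetes",          74,  0.08, 0.65,
    "lung_disease",      82,  0.06, 0.80,
    "arthritis",         71,  0.08, 0.40,
    "parkinsons",        89,  0.10, 0.93,
    "alzheimers",        88,  0.15, 0.85
  )
  shift <- c(hypertension = 0, high_cholesterol = 0, heart_problems = -2,
             stroke = -1, diabetes = -2, lung_disease = -2, arthritis = 3,
             parkinsons = 0, alzheimers = 1)
  dplyr::bind_rows(
    dplyr::mutate(base, sex = "male",
                  x0 = .data$x0 - shift[.data$condition], .before = 1),
    dplyr::mutate(base, sex = "female",
                  x0 = .data$x0 + shift[.data$condition], .before = 1)
  ) |>
    dplyr::select("condition", "sex", "x0", "k", "floor") |>
    dplyr::arrange(.data$condition, .data$sex)
}

#' Default cognition-score generator parameters
#'
#' Scores are on a common standardized scale per test (time orientation,
#' verbal fluency, memory).  Means rise with education and decline
#' linearly with age; the within-stratum SD is 1.  With the default age
#' slope, roughly 5--15\% of respondents at the oldest ages fall below a
#' pooled-reference \eqn{-1.5} SD threshold.
#'
#' @return A list with elements `levels`, `level_probs`, `level_means`,
#'   `age_slope`, `sd`.
#' @export
sim_cognition_params <- function() {
  list(
    levels      = c("low", "medium", "high"),
    level_probs = c(0.35, 0.45, 0.20),
    level_means = c(low = -0.35, medium = 0, high = 0.35),
    age_slope   = 0.035,
    sd          = 1
  )
}

#' Simulate survey-like microdata
#'
#' Generates person-wave records with calibrated-weight-like positive
#' heterogeneous weights, per-condition indicators drawn independently as
#' Bernoulli(1 - free-of-condition probability), cognitive test scores
#' with education-specific means declining with age, and an
#' age-increasing dementia/Alzheimer's diagnosis flag.
#'
#' @param n_per_stratum Records per (wave, sex, age) stratum (>= 1).
#' @param ages Integer ages 60--89 (contiguous single years).
#' @param waves Character wave labels.
#' @param sexes Character sex labels; must match `condition_curves$sex`.
#' @param country Single country code stamped on every record.
#' @param condition_curves Tibble as from [sim_condition_curves()].
#' @param weight_meanlog,weight_sdlog Lognormal parameters for the
#'   calibrated cross-sectional weights (`weight_sdlog = 0` gives equal
#'   weights).  Weights are not normalized within strata: calibrated
#'   weights need not sum to the sample size.
#' @param cognition List as from [sim_cognition_params()].
#' @param dementia_rate60 Diagnosis probability at age 60.
#' @param dementia_slope Exponential age slope of the diagnosis probability.
#' @param seed Integer seed; identical inputs and seed give identical tables.
#' @return A tibble with one row per person-wave: `id`, `wave`, `country`,
#'   `sex`, `age`, `weight`, one logical column per condition,
#'   `cog_orientation`, `cog_fluency`, `cog_memory`, `education`,
#'   `dementia_dx`.
#' @examples
#' md <- sim_survey(n_per_stratum = 5, ages = 60:61, waves = "w1", seed = 42)
#' nrow(md)  # 5 x 2 ages x 2 sexes = 20
#' @export
sim_survey <- function(n_per_stratum = 50,
                       ages = 60:89,
                       waves = "w1",
                       sexes = c("male", "female"),
                       country = "SYN",
                       condition_curves = sim_condition_curves(),
                       weight_meanlog = 0,
                       weight_sdlog = 0.5,
                       cognition = sim_cognition_params(),
                       dementia_rate60 = 0.002,
                       dementia_slope = 0.12,
                       seed = 1L) {
  if (length(n_per_stratum) != 1L || n_per_stratum < 1) {
    abort("`n_per_stratum` must be >= 1.", class = "hl_input_error")
  }
  if (length(ages) == 0 || length(waves) == 0 || length(sexes) == 0) {
    abort("Empty stratum specification: `ages`, `waves` and `sexes` must be non-empty.",
          class = "hl_input_error")
  }
  if (!all(diff(sort(ages)) == 1) || any(ages < 60) || any(ages > 89)) {
    abort("`ages` must be contiguous single years within 60--89.",
          class = "hl_input_error")
  }
  if (weight_sdlog < 0) {
    abort("`weight_sdlog` must be >= 0 (weights strictly positive).",
          class = "hl_input_error")
  }
  conditions <- sort(unique(condition_curves$condition))
  missing_sex <- setdiff(sexes, unique(condition_curves$sex))
  if (length(missing_sex) > 0) {
    abort(sprintf("`condition_curves` lacks rows for sex(es): %s.",
                  paste(missing_sex, collapse = ", ")),
          class = "hl_input_error")
  }

  strata <- tidyr::expand_grid(wave = waves, sex = sexes,
                               age = as.integer(sort(ages)))
  n_tot <- nrow(strata) * n_per_stratum

  with_seed(seed, {
    out <- strata[rep(seq_len(nrow(strata)), each = n_per_stratum), ]
    out$id <- sprintf("P%06d", seq_len(n_tot))
    out$country <- country
    out$weight <- rlnorm(n_tot, weight_meanlog, weight_sdlog)

    # condition indicators: Bernoulli(1 - h_free) per condition, independent
    for (cond in conditions) {
      cc <- condition_curves[condition_curves$condition == cond, ]
      h_free <- rep(NA_real_, n_tot)
      for (s in unique(out$sex)) {
        row <- cc[cc$sex == s, ]
        sel <- out$sex == s
        h_free[sel] <- row$floor +
          (1 - row$floor) / (1 + exp(row$k * (out$age[sel] - row$x0)))
      }
      out[[cond]] <- runif(n_tot) < (1 - h_free)
    }

    out$education <- sample(cognition$levels, n_tot, replace = TRUE,
                            prob = cognition$level_probs)
    mu <- cognition$level_means[out$education] -
      cognition$age_slope * (out$age - 60)
    out$cog_orientation <- rnorm(n_tot, mu, cognition$sd)
    out$cog_fluency     <- rnorm(n_tot, mu, cognition$sd)
    out$cog_memory      <- rnorm(n_tot, mu, cognition$sd)

    p_dem <- pmin(1, dementia_rate60 * exp(dementia_slope * (out$age - 60)))
    out$dementia_dx <- runif(n_tot) < p_dem

    tibble::as_tibble(out[, c("id", "wave", "country", "sex", "age", "weight",
                              conditions, "cog_orientation", "cog_fluency",
                              "cog_memory", "education", "dementia_dx")])
  })
}
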