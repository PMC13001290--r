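# Internal validation helpers shared across modules.
#
# Transient ages are 60..89 (30 single-year age classes); anyone still
# healthy at exact age 90 exits there, so distributions live on 60..90.

hl_transient_ages <- function() 60:89
hl_support_ages <- function() 60:90

# Validate an age-indexed schedule: a data frame with an `age` column and
# one value column, covering `ages` completely (extra key columns allowed,
# but the (age, value) pairs must be unique per age).
check_schedule <- function(x, value_col, ages = hl_transient_ages(),
                           lower = 0, upper = 1,
                           upper_open = TRUE, arg = deparse(substitute(x))) {
  if (!is.data.frame(x)) {
    abort(sprintf("`%s` must be a data frame with columns `age` and `%s`.",
                  arg, value_col), class = "hl_input_error")
  }
  missing_cols <- setdiff(c("age", value_col), names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf("`%s` is missing column(s): %s.", arg,
                  paste0("`", missing_cols, "`", collapse = ", ")),
          class = "hl_input_error")
  }
  missing_ages <- setdiff(ages, x$age)
  if (length(missing_ages) > 0) {
    abort(sprintf("`%s` is missing age(s): %s.", arg,
                  paste(missing_ages, collapse = ", ")),
          class = "hl_input_error")
  }
  if (anyDuplicated(x$age[x$age %in% ages]) > 0) {
    abort(sprintf("`%s` has duplicated ages; supply one row per age.", arg),
          class = "hl_input_error")
  }
  v <- x[[value_col]][match(ages, x$age)]
  if (anyNA(v)) {
    abort(sprintf("`%s` has missing `%s` values.", arg, value_col),
          class = "hl_input_error")
  }
  bad <- v < lower | (if (upper_open) v >= upper else v > upper)
  if (any(bad)) {
    abort(sprintf("`%s`: `%s` out of range %s at age(s) %s.",
                  arg, value_col,
                  sprintf("[%g, %g%s", lower, upper, if (upper_open) ")" else "]"),
                  paste(ages[bad], collapse = ", ")),
          class = "hl_input_error")
  }
  v
}

# Validate a discrete pmf on the 60..90 support; returns the probability
# vector ordered by age.
check_pmf <- function(x, arg = deparse(substitute(x)), tol = 1e-8) {
  value_col <- if (is.data.frame(x) && "phloss" %in% names(x)) "phloss" else "p"
  p <- check_schedule(x, value_col, ages = hl_support_ages(),
                      lower = 0, upper = 1, upper_open = FALSE, arg = arg)
  if (abs(sum(p) - 1) > tol) {
    abort(sprintf("`%s` is not normalized: sum(%s) = %.10f.",
                  arg, value_col, sum(p)),
          class = "hl_input_error")
  }
  p
}

check_number <- function(x, arg, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%g, %g].", arg, lower, upper),
          class = "hl_input_error")
  }
  invisible(x)
}
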