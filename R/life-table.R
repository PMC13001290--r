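# Life-table ingestion: the HMD 1x1 period life-table text layout and a
# simplified long CSV dialect, plus pooling of country schedules into one
# mortality schedule using survey-based country weights.

#' Read a period life table
#'
#' Supports two dialects.  `"hmd"` is the Human Mortality Database 1x1
#' period life-table text layout: two preamble lines, then a whitespace
#' separated table with columns `Year Age mx qx ax lx dx Lx Tx ex`; the
#' open-age `110+` row is accepted and excluded from the returned grid.
#' `"csv"` is a simplified long layout with columns `year, age, sex, qx`.
#' Only single ages 60--89 are returned; a year (or year-sex group)
#' missing any of those ages is an error.
#'
#' @param path Path to the file.
#' @param dialect `"auto"` (default; sniffed from the first line), `"hmd"`
#'   or `"csv"`.
#' @param country Optional country code stamped on the result.
#' @param sex For the HMD dialect (whose files are single-sex), the sex
#'   label to stamp; ignored for CSV, which carries its own column.
#' @return A tibble with columns `country`, `year`, `sex`, `age`, `qx`.
#' @export
read_life_table <- function(path, dialect = c("auto", "hmd", "csv"),
                            country = NA_character_, sex = NA_character_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(sprintf("Life-table file not found: %s", path), class = "hl_input_error")
  }
  if (dialect == "auto") {
    first <- readLines(path, n = 1L)
    dialect <- if (grepl("^\\s*year\\s*,", first, ignore.case = TRUE)) "csv" else "hmd"
  }
  out <- if (dialect == "hmd") {
    parse_hmd_1x1(path, sex = sex)
  } else {
    parse_life_table_csv(path)
  }
  out$country <- country
  out <- out[, c("country", "year", "sex", "age", "qx")]

  # contract: every (year, sex) group must cover single ages 60-89
  grp <- split(out, interaction(out$year, out$sex, drop = TRUE))
  for (g in grp) {
    miss <- setdiff(60:89, g$age)
    if (length(miss) > 0) {
      abort(sprintf("Life table (year %s, sex %s) is missing age(s): %s.",
                    g$year[1], g$sex[1], paste(miss, collapse = ", ")),
            class = "hl_input_error")
    }
  }
  keep <- out$age >= 60 & out$age <= 89
  bad <- out$qx[keep] < 0 | out$qx[keep] > 1 | is.na(out$qx[keep])
  if (any(bad)) {
    abort(sprintf("qx outside [0, 1] (or missing) at age(s): %s.",
                  paste(out$age[keep][bad], collapse = ", ")),
          class = "hl_input_error")
  }
  tibble::as_tibble(out[keep, ]) |>
    dplyr::arrange(.data$year, .data$sex, .data$age)
}

parse_hmd_1x1 <- function(path, sex = NA_character_) {
  lines <- readLines(path)
  header <- grep("^\\s*Year\\s+Age\\s+mx\\s+qx", lines)
  if (length(header) != 1L) {
    abort("Not an HMD 1x1 life table: header line `Year Age mx qx ...` not found.",
          class = "hl_input_error")
  }
  body <- lines[-seq_len(header)]
  body <- body[nzchar(trimws(body))]
  fields <- strsplit(trimws(body), "\\s+")
  n_fields <- lengths(fields)
  if (any(n_fields != 10L)) {
    abort(sprintf("Malformed HMD row (expected 10 fields): %s",
                  body[which(n_fields != 10L)[1]]),
          class = "hl_input_error")
  }
  year <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 1L)))
  age_raw <- vapply(fields, `[[`, "", 2L)
  open_age <- grepl("\\+$", age_raw)           # "110+" parsed, then dropped
  age <- suppressWarnings(as.integer(sub("\\+$", "", age_raw)))
  qx <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L)))
  if (anyNA(year) || anyNA(age)) {
    abort(sprintf("Malformed HMD row: %s", body[which(is.na(year) | is.na(age))[1]]),
          class = "hl_input_error")
  }
  tibble::tibble(year = year, sex = sex, age = age, qx = qx)[!open_age, ]
}

parse_life_table_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  names(df) <- tolower(names(df))
  need <- c("year", "age", "sex", "qx")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(sprintf("Simplified life-table CSV is missing column(s): %s.",
                  paste(miss, collapse = ", ")), class = "hl_input_error")
  }
  tibble::tibble(year = as.integer(df$year), sex = as.character(df$sex),
                 age = as.integer(df$age), qx = as.numeric(df$qx))
}

#' Write a life table in the simplified CSV dialect
#'
#' Canonical serialization (`year,age,sex,qx` with default R number
#' formatting); `read_life_table()` then `write_life_table()` round-trips
#' such files bit-exactly.
#'
#' @param x Tibble with columns `year`, `age`, `sex`, `qx`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_life_table <- function(x, path) {
  lines <- c("year,age,sex,qx",
             paste(x$year, x$age, x$sex,
                   vapply(x$qx, format, "", scientific = FALSE, digits = 15),
                   sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Pool country mortality schedules with survey weights
#'
#' Pooled \eqn{q_x} across countries as a weighted average, the weight of
#' each country being its (weighted) respondent count for that stratum:
#' \eqn{q_x = \sum_c w_c q_{x,c} / \sum_c w_c}.  Pooling is done within
#' every combination of the non-country key columns shared by the two
#' inputs (e.g. `wave`, `sex`, `age`).
#'
#' @param schedules Tibble of per-country schedules with columns `country`,
#'   `qx`, and key columns such as `age`, `sex`, `wave`.
#' @param weights Tibble with column `country`, a `weight` column, and any
#'   key columns at which the weights vary.
#' @return A tibble with the key columns and pooled `qx`, one row per
#'   stratum, tagged `source = "pooled"`.
#' @export
pool_mortality <- function(schedules, weights) {
  if (!"country" %in% names(schedules) || !"country" %in% names(weights)) {
    abort("Both `schedules` and `weights` need a `country` column.",
          class = "hl_input_error")
  }
  if (!"weight" %in% names(weights)) {
    abort("`weights` needs a `weight` column.", class = "hl_input_error")
  }
  miss <- setdiff(unique(schedules$country), unique(weights$country))
  if (length(miss) > 0) {
    abort(sprintf("No weights for country(ies): %s.", paste(miss, collapse = ", ")),
          class = "hl_input_error")
  }
  join_cols <- intersect(setdiff(names(schedules), "qx"),
                         setdiff(names(weights), "weight"))
  # pooling strata: every schedule key except country, whether or not the
  # weights vary over it
  key_cols <- setdiff(names(schedules), c("qx", "country"))
  joined <- dplyr::inner_join(schedules, weights, by = join_cols)
  if (nrow(joined) < nrow(schedules)) {
    abort("Some schedule strata have no matching weight row.",
          class = "hl_input_error")
  }
  out <- joined |>
    dplyr::group_by(dplyr::across(dplyr::all_of(key_cols))) |>
    dplyr::summarise(w_tot = sum(.data$weight),
                     qx = sum(.data$weight * .data$qx), .groups = "drop")
  if (any(out$w_tot <= 0)) {
    abort("Zero total weight in at least one stratum.", class = "hl_input_error")
  }
  out$qx <- out$qx / out$w_tot
  out$w_tot <- NULL
  out$source <- "pooled"
  out
}
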