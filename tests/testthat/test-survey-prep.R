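# Life-table ingestion, health-measure indicators, weighted prevalence
# and country pooling.

test_that("HMD 1x1 layout parses, keeps 60-89 and tolerates the open-age row", {
  f <- withr::local_tempfile(fileext = ".txt")
  write_toy_hmd(f, qx_fun = function(age) 0.01)
  lt <- read_life_table(f, dialect = "hmd", country = "TOY", sex = "male")
  expect_equal(nrow(lt), 30)
  expect_equal(lt$age, 60:89)
  expect_true(all(abs(lt$qx - 0.01) < 1e-12))
  expect_false(110 %in% lt$age)

  # auto-sniffing picks the HMD dialect
  lt2 <- read_life_table(f, sex = "male")
  expect_equal(lt2$qx, lt$qx)
})

test_that("missing ages and malformed rows are rejected by name", {
  f <- withr::local_tempfile(fileext = ".txt")
  write_toy_hmd(f, ages = setdiff(0:110, 75))
  expect_error(read_life_table(f, dialect = "hmd", sex = "male"),
               "75", class = "hl_input_error")

  f2 <- withr::local_tempfile(fileext = ".txt")
  write_toy_hmd(f2)
  lines <- readLines(f2)
  lines[10] <- "  1990  bad row here"
  writeLines(lines, f2)
  expect_error(read_life_table(f2, dialect = "hmd", sex = "male"),
               class = "hl_input_error")

  f3 <- withr::local_tempfile(fileext = ".txt")
  write_toy_hmd(f3, qx_fun = function(age) ifelse(age == 70, 1.5, 0.01))
  expect_error(read_life_table(f3, dialect = "hmd", sex = "male"),
               "70", class = "hl_input_error")
})

test_that("simplified CSV dialect round-trips bit-exactly", {
  lt <- tibble::tibble(year = 1990L, age = 60:89, sex = "female",
                       qx = round(seq(0.005, 0.15, length.out = 30), 6))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_life_table(lt, f1)
  parsed <- read_life_table(f1, dialect = "csv", country = "TOY")
  write_life_table(parsed, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(parsed$qx, lt$qx)
})

test_that("health indicator modes implement the stated rules", {
  md <- tibble::tibble(
    id = as.character(1:4), wave = "w1", sex = "male", age = 70L, weight = 1,
    a = c(FALSE, TRUE, TRUE, FALSE), b = c(FALSE, FALSE, TRUE, FALSE),
    c = c(FALSE, FALSE, TRUE, TRUE))
  all_free <- health_measure("all-free", c("a", "b", "c"))
  at_most <- health_measure("at-most-one", c("a", "b", "c"))
  expect_equal(derive_health_indicator(md, all_free)$healthy,
               c(TRUE, FALSE, FALSE, FALSE))
  # no condition or exactly one -> healthy; two or more -> unhealthy
  expect_equal(derive_health_indicator(md, at_most)$healthy,
               c(TRUE, TRUE, FALSE, TRUE))

  # missing indicators: dropped by default, condition-absent on request
  md$a[1] <- NA
  expect_message(
    out <- derive_health_indicator(md, all_free),
    "dropped 1")
  expect_equal(nrow(out), 3)
  out2 <- derive_health_indicator(md, all_free, missing_conditions = "absent")
  expect_equal(nrow(out2), 4)
  expect_true(out2$healthy[1])
})

test_that("cognitive threshold rule: -1.5 SD per test, dementia overrides", {
  set.seed(1)
  n <- 400
  md <- tibble::tibble(
    id = as.character(1:n), wave = rep(c("w1", "w2"), each = n / 2),
    sex = "female", age = 70L, weight = 1,
    cog_orientation = rnorm(n), cog_fluency = rnorm(n), cog_memory = rnorm(n),
    education = sample(c("low", "high"), n, replace = TRUE),
    dementia_dx = FALSE)
  # scores exactly at the reference mean but a dementia diagnosis: unhealthy
  md$cog_orientation[1] <- mean(md$cog_orientation)
  md$cog_fluency[1] <- mean(md$cog_fluency)
  md$cog_memory[1] <- mean(md$cog_memory)
  md$dementia_dx[1] <- TRUE
  meas <- health_measure("cognitive-threshold")
  out <- derive_health_indicator(md, meas)
  expect_false(out$healthy[1])

  # a record far below threshold on one test only is unhealthy
  md2 <- md; md2$dementia_dx[1] <- FALSE; md2$cog_memory[2] <- -10
  out2 <- derive_health_indicator(md2, meas)
  expect_true(out2$healthy[1])
  expect_false(out2$healthy[2])

  # all scores missing -> dropped with a logged count
  md3 <- md
  md3[1, c("cog_orientation", "cog_fluency", "cog_memory")] <- NA
  expect_message(out3 <- derive_health_indicator(md3, meas), "dropped 1")
  expect_equal(nrow(out3), n - 1)

  # education adjustment changes the reference population
  md4 <- md
  md4$cog_orientation <- md4$cog_orientation + ifelse(md4$education == "high", 2, -2)
  meas_edu <- health_measure("cognitive-threshold", education_adjusted = TRUE)
  plain <- derive_health_indicator(md4, meas)
  adj <- derive_health_indicator(md4, meas_edu)
  expect_false(identical(plain$healthy, adj$healthy))
})

test_that("weighted prevalence is the weight-share of healthy and scale-invariant", {
  md <- tibble::tibble(wave = "w1", sex = "m", age = 60L,
                       weight = c(2, 1, 1), healthy = c(TRUE, FALSE, TRUE))
  pv <- weighted_prevalence(md, ages = 60)
  expect_equal(pv$hx, 0.75)            # (2 + 1) / 4
  expect_equal(pv$n, 3L)
  # invariant to global rescaling of weights within the stratum
  md2 <- dplyr::mutate(md, weight = weight * 37.5)
  expect_equal(weighted_prevalence(md2, ages = 60)$hx, 0.75)
  # equal weights reduce to the unweighted proportion; all healthy gives 1
  md3 <- dplyr::mutate(md, weight = 1)
  expect_equal(weighted_prevalence(md3, ages = 60)$hx, 2 / 3)
  md4 <- dplyr::mutate(md, healthy = TRUE)
  expect_equal(weighted_prevalence(md4, ages = 60)$hx, 1)

  # 90+ records are excluded from the 60-89 schedule; empty strata error
  md5 <- dplyr::bind_rows(md, dplyr::mutate(md, age = 92L))
  expect_equal(nrow(weighted_prevalence(md5, ages = 60)), 1)
  expect_error(weighted_prevalence(md, ages = 60:61), "61",
               class = "hl_input_error")
  expect_error(weighted_prevalence(dplyr::mutate(md, age = 55L), ages = 60),
               class = "hl_input_error")
})

test_that("an all-free measure with an empty unhealthy set gives h = 1 downstream", {
  md <- sim_survey(n_per_stratum = 3, ages = 60:62, waves = "w1", seed = 2)
  md$never <- FALSE
  meas <- health_measure("all-free", "never")
  pv <- weighted_prevalence(derive_health_indicator(md, meas), ages = 60:62)
  expect_true(all(pv$hx == 1))
})

test_that("country pooling averages qx with respondent-count weights", {
  sch <- dplyr::bind_rows(
    tibble::tibble(country = "A", age = 60:61, qx = 0.01),
    tibble::tibble(country = "B", age = 60:61, qx = 0.03))
  w_eq <- tibble::tibble(country = c("A", "B"), weight = 1)
  pooled <- pool_mortality(sch, w_eq)
  expect_equal(pooled$qx, c(0.02, 0.02))
  # weights (3, 1): 0.75 * 0.01 + 0.25 * 0.05 = 0.02
  sch2 <- dplyr::mutate(sch, qx = ifelse(country == "A", 0.01, 0.05))
  pooled2 <- pool_mortality(sch2, tibble::tibble(country = c("A", "B"),
                                                 weight = c(3, 1)))
  expect_equal(pooled2$qx, c(0.02, 0.02))
  # a single country passes through unchanged
  one <- pool_mortality(sch[sch$country == "A", ], w_eq[1, ])
  expect_equal(one$qx, c(0.01, 0.01))
  # per-age weights join on the shared key columns
  w_age <- tibble::tibble(country = rep(c("A", "B"), each = 2),
                          age = rep(60:61, 2), weight = c(1, 1, 1, 3))
  pooled3 <- pool_mortality(sch2, w_age)
  expect_equal(pooled3$qx, c(0.03, 0.04))
  expect_error(pool_mortality(sch, w_eq[1, ]), "B", class = "hl_input_error")
})
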