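# Markov-chain-with-rewards moments: closed forms, identities and
# cross-checks against independent routes.

test_that("deterministic chain: no mortality, always healthy gives 30 years", {
  mort <- tibble::tibble(age = 60:89, qx = 0)
  prev <- tibble::tibble(age = 60:89, hx = 1)
  for (conv in c("occupancy", "survived-year")) {
    mom <- mcwr_moments(mort, prev, convention = conv)
    expect_equal(mom$m1, 30, tolerance = 1e-12)
    expect_equal(mom$variance, 0, tolerance = 1e-12)
    expect_true(mom$degenerate)
    expect_true(is.na(mom$skewness))           # flagged undefined
    expect_equal(mom$hle, 90)
  }
})

test_that("two-age toy (q = 0, h = 0.5 then 0): enumeration moments", {
  # HY = B60 + B61 with independent fair Bernoullis: the four outcome paths
  # give m1 = 1, m2 = 1.5, m3 = 2.5, variance = 0.5, skewness = 0
  mort <- tibble::tibble(age = 60:89, qx = 0)
  prev <- tibble::tibble(age = 60:89, hx = c(0.5, 0.5, rep(0, 28)))
  mom <- mcwr_moments(mort, prev, convention = "occupancy",
                      condition_on_healthy_at_60 = FALSE)
  expect_equal(mom$m1, 1, tolerance = 1e-12)
  expect_equal(mom$m2, 1.5, tolerance = 1e-12)
  expect_equal(mom$m3, 2.5, tolerance = 1e-12)
  expect_equal(mom$variance, 0.5, tolerance = 1e-12)
  expect_equal(mom$skewness, 0, tolerance = 1e-12)
})

test_that("central-moment conversion: hand algebra and degenerate flagging", {
  cm <- central_moments(1, 1.5, 2.5)
  expect_equal(cm$variance, 0.5)
  expect_equal(cm$mu3, 0)                      # 2.5 - 4.5 + 2
  expect_equal(cm$skewness, 0)
  cm0 <- central_moments(0, 0, 0)
  expect_equal(cm0$variance, 0)
  expect_true(cm0$degenerate)
  # symmetric pmf on {0,1,2} with p = (1/4, 1/2, 1/4)
  m <- moments_from_pmf(c(0.25, 0.5, 0.25))
  cms <- central_moments(m["m1"], m["m2"], m["m3"])
  expect_equal(cms$skewness, 0, tolerance = 1e-12)
  expect_error(central_moments(2, 1, 5), class = "hl_infeasible_error")
})

test_that("occupancy m1 equals the Sullivan-type sum to 1e-12", {
  for (i in 1:10) {
    sch <- with_seed_local(100 + i, random_schedules())
    mom <- mcwr_moments(sch$mortality, sch$prevalence)
    qx <- sch$mortality$qx
    hx <- sch$prevalence$hx; hx[1] <- 1        # conditioned on healthy at 60
    lx <- cumprod(c(1, 1 - qx[-30]))
    expect_equal(mom$m1, sum(lx * hx), tolerance = 1e-12)
    expect_equal(sullivan_hle(sch$mortality, sch$prevalence), sum(lx * hx),
                 tolerance = 1e-12)
  }
})

test_that("all three moments match the forward dynamic-programming oracle", {
  for (i in 1:10) {
    sch <- with_seed_local(200 + i, random_schedules())
    for (conv in c("occupancy", "survived-year")) {
      for (cond in c(TRUE, FALSE)) {
        mom <- mcwr_moments(sch$mortality, sch$prevalence, convention = conv,
                            condition_on_healthy_at_60 = cond)
        pmf <- dp_exit_pmf(sch$mortality$qx, sch$prevalence$hx, conv, cond)
        m <- moments_from_pmf(pmf)
        expect_equal(mom$m1, unname(m["m1"]), tolerance = 1e-12)
        expect_equal(mom$m2, unname(m["m2"]), tolerance = 1e-12)
        expect_equal(mom$m3, unname(m["m3"]), tolerance = 1e-12)
      }
    }
  }
})

test_that("moments agree with Monte-Carlo simulation within 4 SEs", {
  # scaled-down version of the cross-module property (full scale runs in
  # the acceptance suite)
  for (i in 1:3) {
    sch <- with_seed_local(300 + i, random_schedules())
    for (conv in c("occupancy", "survived-year")) {
      mom <- mcwr_moments(sch$mortality, sch$prevalence, convention = conv)
      orc <- simulate_healthy_years(sch$mortality, sch$prevalence,
                                    convention = conv, n_sim = 2e5,
                                    seed = 1000 + i)
      analytic <- c(mom$m1, mom$m2, mom$m3)
      expect_true(all(abs(orc$moments$value - analytic) < 4 * orc$moments$se),
                  label = sprintf("schedule %d, %s within 4 SE", i, conv))
    }
  }
})

test_that("monotonicity and convention ordering", {
  sch <- with_seed_local(55, random_schedules())
  base <- mcwr_moments(sch$mortality, sch$prevalence)
  # raising any single h_x never decreases the mean
  for (j in c(1, 15, 30)) {
    prev_up <- sch$prevalence
    prev_up$hx[j] <- min(1, prev_up$hx[j] + 0.1)
    expect_gte(mcwr_moments(sch$mortality, prev_up)$m1, base$m1 - 1e-12)
  }
  # a reward that requires surviving the year cannot exceed occupancy
  sv <- mcwr_moments(sch$mortality, sch$prevalence, convention = "survived-year")
  expect_lte(sv$m1, base$m1)
})

test_that("tidy and glance expose the published summaries", {
  sch <- with_seed_local(77, random_schedules())
  mom <- mcwr_moments(sch$mortality, sch$prevalence)
  td <- tidy(mom)
  expect_named(td, c("m1", "m2", "m3", "hle", "sdhl", "skewness"))
  expect_equal(td$hle, 60 + td$m1)
  expect_equal(td$sdhl, sqrt(td$m2 - td$m1^2), tolerance = 1e-12)
  gl <- glance(mom)
  expect_false(gl$degenerate)
  expect_equal(gl$convention, "occupancy")
})

test_that("schedule gaps and out-of-range inputs are rejected", {
  mort <- tibble::tibble(age = 60:89, qx = 0.01)
  prev <- tibble::tibble(age = 60:89, hx = 0.9)
  expect_error(mcwr_moments(mort[-5, ], prev), "64", class = "hl_input_error")
  expect_error(mcwr_moments(dplyr::mutate(mort, qx = 1), prev),
               class = "hl_input_error")
  expect_error(mcwr_moments(mort, dplyr::mutate(prev, hx = 1.2)),
               class = "hl_input_error")
})
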