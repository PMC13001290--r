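# Maximum-entropy reconstruction of the exit-age distribution.

test_that("uniform moments recover the uniform pmf with zero multipliers", {
  # discrete uniform on 60..90: healthy-years mean 15, variance 80, skew 0
  hy <- 0:30
  m <- moments_from_pmf(rep(1 / 31, 31), hy)
  fit <- solve_maxent(list(m1 = m[["m1"]], m2 = m[["m2"]], m3 = m[["m3"]]))
  expect_true(fit$converged)
  expect_equal(fit$pmf$phloss, rep(1 / 31, 31), tolerance = 1e-8)
  expect_equal(unname(fit$lambda), c(0, 0, 0), tolerance = 1e-6)
  expect_equal(fit$iterations, 0L)
})

test_that("degenerate variance yields the forced point mass", {
  fit <- solve_maxent(list(m1 = 30, m2 = 900, m3 = 27000))
  expect_true(fit$degenerate)
  expect_equal(fit$pmf$phloss[fit$pmf$age == 90], 1)
  expect_equal(fit$mode_age, 90L)
  fit2 <- solve_maxent(list(m1 = 10, m2 = 100, m3 = 1000))
  expect_equal(fit2$pmf$phloss[fit2$pmf$age == 70], 1)
})

test_that("fitted distributions are normalized and recover their moments", {
  for (i in 1:12) {
    sch <- with_seed_local(400 + i, random_schedules())
    mom <- mcwr_moments(sch$mortality, sch$prevalence)
    fit <- solve_maxent(mom)
    p <- fit$pmf$phloss
    hy <- fit$pmf$age - 60
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-10)
    # moment recovery on mean / variance / skewness scale
    mean_fit <- sum(p * hy)
    var_fit <- sum(p * (hy - mean_fit)^2)
    skew_fit <- sum(p * (hy - mean_fit)^3) / var_fit^1.5
    expect_equal(mean_fit, mom$mean, tolerance = 1e-6)
    expect_equal(var_fit, mom$variance, tolerance = 1e-6)
    expect_equal(skew_fit, mom$skewness, tolerance = 1e-6)
  }
})

test_that("symmetric moment sets give symmetric distributions", {
  # centred at 75 so the 60..90 support is symmetric about the mean
  for (v in c(20, 45, 70)) {
    fit <- solve_maxent(list(m1 = 15, m2 = v + 225, m3 = 15^3 + 3 * 15 * v))
    p <- fit$pmf$phloss
    expect_equal(p, rev(p), tolerance = 1e-8)
  }
})

test_that("restarting from different initial multipliers is irrelevant: the dual is strictly convex", {
  sch <- with_seed_local(91, random_schedules())
  mom <- mcwr_moments(sch$mortality, sch$prevalence)
  fit <- solve_maxent(mom)
  # re-fit from the solution's own moments: same distribution again
  hy <- fit$pmf$age - 60
  p <- fit$pmf$phloss
  refit <- solve_maxent(list(m1 = sum(p * hy), m2 = sum(p * hy^2),
                             m3 = sum(p * hy^3)))
  expect_equal(refit$pmf$phloss, fit$pmf$phloss, tolerance = 1e-8)
})

test_that("solver entropy beats feasible pmfs found by constrained random search", {
  sch <- with_seed_local(92, random_schedules())
  mom <- mcwr_moments(sch$mortality, sch$prevalence)
  fit <- solve_maxent(mom)
  p0 <- fit$pmf$phloss
  h_fit <- entropy_of(p0)
  # random feasible competitors: move from the solution along directions in
  # the null space of the constraint matrix (same normalization and three
  # moments exactly), stepping half-way to the nonnegativity boundary
  z <- (0:30 - mom$mean) / sqrt(mom$variance)
  A <- rbind(1, z, z^2, z^3)
  N <- null_space(A)
  found <- 0
  with_seed_local(93, {
    for (try in 1:200) {
      d <- drop(N %*% rnorm(ncol(N)))
      neg <- d < 0
      t_max <- min(p0[neg] / -d[neg])
      p <- p0 + 0.5 * t_max * d
      expect_equal(drop(A %*% p), drop(A %*% p0), tolerance = 1e-9)
      if (max(abs(p - p0)) > 1e-8) {
        found <- found + 1
        expect_lte(entropy_of(p), h_fit + 1e-10)
      }
    }
  })
  expect_gt(found, 0)    # the search actually produced feasible competitors
})

test_that("infeasible moment sets raise a feasibility error, not a silent fit", {
  # mean outside the support
  expect_error(solve_maxent(list(m1 = 40, m2 = 1700, m3 = 70000)),
               class = "hl_infeasible_error")
  # variance above the two-point bound (mean-60)(90-mean)
  expect_error(solve_maxent(list(m1 = 15, m2 = 230 + 225, m3 = 3500)),
               class = "hl_infeasible_error")
  # m2 < m1^2
  expect_error(solve_maxent(list(m1 = 10, m2 = 50, m3 = 1000)),
               class = "hl_infeasible_error")
})

test_that("survival curve, mode and tie-breaking follow the stated rules", {
  u <- tibble::tibble(age = 60:90, phloss = rep(1 / 31, 31))
  sv <- health_survival(u)
  expect_equal(sv$lhealth[sv$age == 60], 1)
  expect_equal(sv$lhealth[sv$age == 91], 0)
  expect_equal(sv$lhealth, c((91 - 60:90) / 31, 0), tolerance = 1e-12)

  pm <- point_mass_pmf(90)
  expect_true(all(health_survival(pm)$lhealth[1:31] == 1))

  two <- tibble::tibble(age = 60:90, phloss = c(0.5, 0.5, rep(0, 29)))
  sv2 <- health_survival(two)
  expect_equal(sv2$lhealth[sv2$age == 61], 0.5)
  expect_equal(sv2$lhealth[sv2$age == 62], 0)

  # mode: ties broken to the smallest age; point masses are their own mode
  expect_equal(dist_mode(u)$mode_age, 60)
  md <- dist_mode(point_mass_pmf(86))
  expect_equal(md$mode_age, 86)
  expect_equal(md$mode_prob, 1)
})

test_that("tail diagnostic reports signed differences and TV distance", {
  u <- tibble::tibble(age = 60:90, phloss = rep(1 / 31, 31))
  d0 <- tail_diagnostic(u, u)
  expect_equal(d0$tv, 0)
  expect_true(all(d0$by_age$diff == 0))
  d1 <- tail_diagnostic(point_mass_pmf(60), point_mass_pmf(90))
  expect_equal(d1$tv, 1)

  # against the Monte-Carlo oracle on a synthetic schedule: finite TV and
  # the moment-matched fit reproduces the oracle only approximately
  sch <- with_seed_local(94, random_schedules())
  mom <- mcwr_moments(sch$mortality, sch$prevalence)
  fit <- solve_maxent(mom)
  orc <- simulate_healthy_years(sch$mortality, sch$prevalence, n_sim = 5e4,
                                seed = 95)
  dg <- tail_diagnostic(fit$pmf[c("age", "phloss")], orc$pmf[c("age", "p")])
  expect_gt(dg$tv, 0)
  expect_lt(dg$tv, 0.5)
  expect_equal(glance(dg)$tv, dg$tv)
})
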