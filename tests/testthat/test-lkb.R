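test_that("fraction-size correction matches the linear-quadratic closed form", {
  expect_equal(lqed2(56, 28, 10), 56)               # 2 Gy/fraction identity
  expect_equal(lqed2(28, 28, 10), 28 * 1.1 / 1.2)   # 1 Gy/fraction, a/b = 10
  expect_equal(lqed2(0, 28, 10), 0)
  expect_error(lqed2(10, 0, 10), ">= 1")

  # identity at 2 Gy per fraction holds to machine precision (doses of at
  # least 2 Gy, so the fraction count stays >= 1)
  set.seed(1)
  di <- stats::runif(200, 2.5, 80)
  for (d in di) expect_equal(lqed2(d, d / 2, 10), d, tolerance = 1e-13)
})

test_that("effective dose reduces the DVH as a generalized mean", {
  # uniform dose at 2 Gy/fraction with n = 1 returns the dose itself
  ph <- plan_phase(list(whole_pelvis = dvh(44, 1)), 22)
  expect_equal(deff(ph, "whole_pelvis", lkb_params(n = 1)), 44)

  # with a huge alpha/beta the correction vanishes and Deff is the plain
  # generalized mean of the bin doses
  raw <- lkb_params(n = 1, alpha_beta = 1e12)
  ph2 <- plan_phase(list(whole_pelvis = dvh(c(20, 40), c(0.5, 0.5))), 10)
  expect_equal(deff(ph2, "whole_pelvis", raw), 30, tolerance = 1e-9)
  raw05 <- lkb_params(n = 0.5, alpha_beta = 1e12)
  expect_equal(deff(ph2, "whole_pelvis", raw05),
               (0.5 * 20^2 + 0.5 * 40^2)^0.5, tolerance = 1e-9)
  expect_equal(deff(ph2, "whole_pelvis", raw05), 31.6228, tolerance = 1e-4)

  expect_error(deff(ph2, "iliac"), "not present")

  # n = 1 equals the volume-weighted mean corrected dose on random DVHs
  set.seed(21)
  for (i in 1:20) {
    d <- random_dvh()
    phx <- plan_phase(stats::setNames(list(d), d$structure), 25)
    want <- sum(d$volume_fraction * lqed2(d$dose_gy, 25, 10)) / sum(d$volume_fraction)
    expect_equal(deff(phx, d$structure, lkb_params(n = 1)), want, tolerance = 1e-12)
  }
})

test_that("multi-phase effective dose is the sum of per-phase values", {
  p1 <- plan_phase(list(whole_pelvis = dvh(15, 1)), 7.5)  # 2 Gy/fraction
  p2 <- plan_phase(list(whole_pelvis = dvh(15, 1)), 7.5)
  expect_equal(deff_plan(list(p1, p2), "whole_pelvis"), 30)
  expect_equal(deff_plan(list(p1), "whole_pelvis"), deff(p1, "whole_pelvis"))
  p3 <- plan_phase(list(whole_pelvis = dvh(c(10, 20), c(0.3, 0.7))), 11)
  expect_equal(deff_plan(list(p1, p3), "whole_pelvis"),
               deff_plan(list(p3, p1), "whole_pelvis"))
  expect_error(deff_plan(list(), "whole_pelvis"), "at least one phase")
})

test_that("the probit dose-response hits its landmarks", {
  pars <- lkb_params(m = 0.09, td50 = 30)
  expect_equal(ntcp(30, pars)$ntcp, 0.5)
  expect_equal(ntcp(30, pars)$x, 0)
  expect_equal(ntcp(32.7, pars)$x, 1, tolerance = 1e-12)
  expect_equal(ntcp(32.7, pars)$ntcp, 0.841345, tolerance = 1e-6)
  expect_equal(ntcp(27.3, pars)$ntcp, 1 - ntcp(32.7, pars)$ntcp, tolerance = 1e-12)

  # strictly increasing in Deff (away from double-precision saturation of
  # the normal CDF); NTCP(TD50) = 0.5 for any slope
  d <- seq(22, 38, by = 0.5)
  expect_true(all(diff(ntcp(d, pars)) > 0))
  for (m in c(0.01, 0.09, 0.5))
    expect_equal(ntcp(30, lkb_params(m = m, td50 = 30))$ntcp, 0.5)
})

test_that("parameter-CI NTCP bands behave monotonically and contain the point", {
  degen <- lkb_params(m = 0.09, td50 = 30, m_ci = c(0.09, 0.09),
                      td50_ci = c(30, 30))
  expect_equal(ntcp_interval(31, degen), rep(ntcp(31, degen)$ntcp, 2))

  pars <- lkb_params(m = 0.09, td50 = 30, m_ci = c(0.09, 0.09),
                     td50_ci = c(28, 32))
  band <- ntcp_interval(30, pars)
  expect_true(band[1] < 0.5 && band[2] > 0.5)

  narrow <- lkb_params(m_ci = c(0.08, 0.10), td50_ci = c(28, 32))
  wide <- lkb_params(m_ci = c(0.05, 0.20), td50_ci = c(28, 32))
  for (d in c(22, 30, 38)) {
    bn <- ntcp_interval(d, narrow); bw <- ntcp_interval(d, wide)
    expect_true(bw[1] <= bn[1] + 1e-12 && bw[2] >= bn[2] - 1e-12)
    pt <- ntcp(d, narrow, with_ci = FALSE)$ntcp
    expect_true(bn[1] <= pt && pt <= bn[2])
  }
  expect_error(ntcp_interval(30, lkb_params(m_ci = NULL)), "required")
})

test_that("maximum-likelihood fitting recovers generating parameters", {
  set.seed(100)
  d <- stats::runif(2000, 20, 40)
  y <- stats::runif(2000) < ntcp(d, lkb_params(m = 0.09, td50 = 30), with_ci = FALSE)
  fit <- fit_lkb_ml(d, y, compute_ci = FALSE)
  expect_lt(abs(fit$m - 0.09), 0.03)
  expect_lt(abs(fit$td50 - 30), 1.5)

  # shifted truth is recovered near the shifted value, not the default
  y35 <- stats::runif(2000) < ntcp(d, lkb_params(m = 0.09, td50 = 35), with_ci = FALSE)
  fit35 <- fit_lkb_ml(d, y35, compute_ci = FALSE)
  expect_lt(abs(fit35$td50 - 35), 1.5)
  expect_gt(fit35$td50, 32.5)

  # fitted likelihood dominates a coarse grid over the search box
  ll_fit <- attr(fit, "loglik")
  grid <- expand.grid(m = seq(0.02, 0.5, length.out = 25),
                      td50 = seq(20, 45, length.out = 25))
  ll_grid <- mapply(function(m, t) {
    p <- pmin(pmax(stats::pnorm((d - t) / (m * t)), 1e-12), 1 - 1e-12)
    sum(y * log(p) + (1 - y) * log(1 - p))
  }, grid$m, grid$td50)
  expect_gte(ll_fit, max(ll_grid) - 1e-6)

  expect_error(fit_lkb_ml(d, rep(0, 2000)), "not identifiable")
  expect_error(fit_lkb_ml(c(-1, 2), c(0, 1)), "positive")
})

test_that("profile-likelihood intervals bracket the estimate and the truth scale", {
  set.seed(101)
  d <- stats::runif(800, 20, 40)
  y <- stats::runif(800) < ntcp(d, lkb_params(m = 0.09, td50 = 30), with_ci = FALSE)
  fit <- fit_lkb_ml(d, y)
  expect_true(fit$m_ci[1] <= fit$m && fit$m <= fit$m_ci[2])
  expect_true(fit$td50_ci[1] <= fit$td50 && fit$td50 <= fit$td50_ci[2])
  expect_lt(fit$td50_ci[2] - fit$td50_ci[1], 10)
})
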