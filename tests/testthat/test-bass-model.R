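test_that("parameter validation enforces the model's domain", {
  expect_error(bass_params(p = 0, q = 0.1), "p")
  expect_error(bass_params(p = 0.01, q = -0.1), "q")
  expect_error(bass_params(p = 0.01, q = 0.1, m = 1.5), "m")
  expect_s3_class(bass_params(p = 0.01, q = 0), "bass_params")
})

test_that("closed-form curve starts at zero, increases, and saturates at m", {
  cases <- list(
    bass_params(0.002, 0.268, 1, 2001),
    bass_params(0.0071, 0.214, 1, 2004),
    bass_params(0.1, 0.001, 1, 2000),   # inverse-J regime
    bass_params(0.01, 0.3, 0.8, 2000)   # sub-unit market potential
  )
  for (pars in cases) {
    expect_identical(bass_cdf(pars, 0), 0)
    grid <- seq(0, 60, by = 0.5)
    f <- bass_cdf(pars, grid)
    expect_true(all(diff(f) > 0))
    expect_true(all(f >= 0 & f < pars$m))
    expect_gt(bass_cdf(pars, 1000), pars$m - 1e-6)
  }
  expect_error(bass_cdf(cases[[1]], -1), "nonnegative")
})

test_that("q = 0 reduces to the pure-external exponential model", {
  pars <- bass_params(p = 0.01, q = 0, m = 1, start_year = 2000)
  tt <- c(0, 1, 5, 10, 50)
  expect_equal(bass_cdf(pars, tt), 1 - exp(-0.01 * tt), tolerance = 1e-15)
  expect_equal(bass_cdf(pars, 10), 1 - exp(-0.1))
  pars_m <- bass_params(p = 0.02, q = 0, m = 0.6, start_year = 2000)
  expect_equal(bass_cdf(pars_m, tt), 0.6 * (1 - exp(-0.02 * tt)),
               tolerance = 1e-15)
})

test_that("adoption rate matches the central finite difference of the cdf", {
  h <- 1e-5
  for (pars in list(bass_params(0.002, 0.268, 1, 2001),
                    bass_params(0.018, 0.095, 1, 2007),
                    bass_params(0.01, 0, 0.9, 2000))) {
    tt <- seq(0.1, 40, by = 0.7)
    fd <- (bass_cdf(pars, tt + h) - bass_cdf(pars, tt - h)) / (2 * h)
    expect_equal(bass_rate(pars, tt), fd, tolerance = 1e-6)
    expect_true(all(bass_rate(pars, tt) >= 0))
  }
  # rate at the origin of the q = 0 model is p * m
  expect_equal(bass_rate(bass_params(0.01, 0, 1, 2000), 0), 0.01)
  expect_equal(bass_rate(bass_params(0.01, 0, 0.5, 2000), 0), 0.005)
})

test_that("discrete recursion steps as specified and converges to the cdf", {
  pars <- bass_params(p = 0.002, q = 0.268, m = 1, start_year = 2001)
  traj <- bass_discrete_trajectory(pars, 2)
  # first annual increment is p * m; second follows the hand recursion
  expect_equal(traj$cumulative_fraction[2], 0.002)
  # 0.002 + (0.002 + 0.268 * 0.002) * 0.998 carried to full precision
  expect_equal(traj$cumulative_fraction[3], 0.004530928, tolerance = 1e-8)
  # nondecreasing and bounded
  long <- bass_discrete_trajectory(pars, 200)
  expect_true(all(diff(long$cumulative_fraction) >= 0))
  expect_true(all(long$cumulative_fraction <= pars$m))
  # sub-annual refinement converges to the continuous closed form
  horizon <- 20
  err <- vapply(c(1, 20, 400), function(spy) {
    tr <- bass_discrete_trajectory(pars, horizon * spy, steps_per_year = spy)
    abs(utils::tail(tr$cumulative_fraction, 1) - bass_cdf(pars, horizon))
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 1e-3)
})

test_that("inflection time maximizes the adoption rate when q > p", {
  pars <- bass_params(p = 0.214 / 30.092, q = 0.214, m = 1,
                      start_year = 2004)
  tstar <- bass_inflection_time(pars)
  expect_equal(tstar, 15.40, tolerance = 0.01 / 15.40)
  # grid-maximization oracle: the rate is largest at the analytic optimum
  grid <- seq(0.01, 60, by = 0.01)
  expect_true(all(bass_rate(pars, tstar) >= bass_rate(pars, grid)))
  # no interior inflection in the monotone-decelerating regime
  expect_true(is.na(bass_inflection_time(bass_params(0.1, 0.1, 1, 2000))))
  expect_true(is.na(bass_inflection_time(bass_params(0.01, 0, 1, 2000))))
})

test_that("time to threshold inverts the cdf", {
  pars <- bass_params(p = 0.268 / 117.040, q = 0.268, m = 1,
                      start_year = 2001)
  # bisection oracle frozen: F reaches 50% at t = 17.68
  expect_equal(bass_time_to_threshold(pars, 0.5), 17.68,
               tolerance = 0.01 / 17.68)
  expect_identical(bass_time_to_threshold(pars, 0), 0)
  # inverse-function roundtrip at several interior points
  for (t0 in c(0.5, 3, 8.3, 25)) {
    expect_equal(bass_time_to_threshold(pars, bass_cdf(pars, t0)), t0,
                 tolerance = 1e-9)
  }
  expect_error(bass_time_to_threshold(pars, 1), "unreachable")
  pm <- bass_params(0.01, 0.2, 0.7, 2000)
  expect_error(bass_time_to_threshold(pm, 0.7), "unreachable")
  expect_equal(bass_cdf(pm, bass_time_to_threshold(pm, 0.5)), 0.5,
               tolerance = 1e-12)
})

test_that("curve shape and motivation ratio follow the q vs p comparison", {
  expect_identical(bass_shape(bass_params(0.00229, 0.268, 1, 2001)),
                   "s_curve")
  expect_identical(bass_shape(bass_params(0.1, 0.001, 1, 2001)), "inverse_j")
  # boundary tie-break: q == p is not an S-curve
  expect_identical(bass_shape(bass_params(0.05, 0.05, 1, 2001)), "inverse_j")
  expect_equal(motivation_ratio(bass_params(0.0071115, 0.214, 1, 2004)),
               30.092, tolerance = 0.01 / 30.092)
  expect_identical(motivation_ratio(bass_params(0.01, 0, 1, 2001)), 0)
  # rounded published p is inconsistent with the published ratio: dividing
  # q = 0.268 by the 3-dp p gives 134, not 117.040 — the ratio anchors p
  expect_equal(motivation_ratio(bass_params(0.002, 0.268, 1, 2001)), 134)
})

test_that("calendar trajectories are zero before the start year", {
  pars <- bass_params(0.007, 0.214, 1, 2004)
  traj <- bass_trajectory(pars, 2001:2010)
  expect_identical(traj$cumulative_fraction[traj$year <= 2004],
                   rep(0, 4))
  expect_equal(traj$cumulative_fraction[traj$year == 2008],
               bass_cdf(pars, 4))
  expect_equal(traj$percent, 100 * traj$cumulative_fraction)
})
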