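test_that("noise-free series on an exact Bass curve are recovered", {
  truth <- bass_params(p = 0.005, q = 0.25, m = 1, start_year = 2004)
  ser <- data.frame(year = c(2008, 2011, 2013),
                    fraction = bass_cdf(truth, c(4, 7, 9)))
  fit <- bass_fit(ser, start_year = 2004)
  expect_lt(abs(coef(fit)["p"] - 0.005), 1e-4)
  expect_lt(abs(coef(fit)["q"] - 0.25), 1e-4)
  expect_lt(fit$objective, 1e-12)
  expect_true(fit$feasible)
})

test_that("recovery holds across a grid of true parameter pairs", {
  for (p0 in c(0.002, 0.01, 0.05)) {
    for (q0 in c(0.1, 0.25, 0.4)) {
      truth <- bass_params(p0, q0, 1, 2004)
      ser <- data.frame(year = c(2008, 2011, 2013),
                        fraction = bass_cdf(truth, c(4, 7, 9)))
      fit <- bass_fit(ser, start_year = 2004)
      expect_lt(abs(coef(fit)["p"] - p0), 1e-3)
      expect_lt(abs(coef(fit)["q"] - q0), 1e-3)
    }
  }
})

test_that("an exactly identified two-point fit interpolates", {
  fit <- bass_fit(mu_targets(), start_year = 2004)
  expect_lt(max(abs(fit$residuals)), 1e-8)   # percentage points
  expect_true(fit$feasible)
})

test_that("the observed uptake series yields a feasible contagion-dominated fit", {
  fit <- bass_fit(hints_series(), start_year = 2001)
  expect_true(fit$feasible)
  expect_true(all(abs(fit$residuals) <= 2))          # pp scale
  expect_gt(fit$q_over_p, 100)                       # order of hundreds
  expect_lt(fit$q_over_p, 1000)
  expect_identical(bass_shape(fit$params), "s_curve")
  # feasibility flag is definitionally tied to the band
  expect_identical(fit$feasible,
                   max(abs(fit$residuals)) / 100 <= fit$band + 1e-12)
})

test_that("fitting is deterministic and beats every grid start it scanned", {
  ser <- hints_series()
  f1 <- bass_fit(ser, start_year = 2001)
  f2 <- bass_fit(ser, start_year = 2001)
  f1$call <- f2$call <- NULL
  expect_identical(f1, f2)
  # objective no worse than a direct scan of candidate grid points
  sse_at <- function(p, q) {
    pred <- bass_cdf(bass_params(p, q, 1, 2001), ser$year - 2001)
    sum((pred - ser$fraction)^2)
  }
  grid_sse <- outer(exp(seq(log(1e-6), log(0.5), length.out = 40)),
                    seq(1e-12, 1, length.out = 40), Vectorize(sse_at))
  expect_lte(f1$objective, min(grid_sse))
})

test_that("fit validates its inputs", {
  ser <- hints_series()
  expect_error(bass_fit(ser[1, , drop = FALSE], 2001), "at least 2")
  expect_error(bass_fit(ser, start_year = 2008), "strictly after")
  expect_error(bass_fit(ser, start_year = 2010), "strictly after")
  flat <- data.frame(year = c(2008, 2011, 2013), fraction = rep(0.1, 3))
  expect_warning(
    expect_warning(bass_fit(flat, 2001), "not strictly increasing"),
    "band|residuals"
  )
})

test_that("start-date sensitivity shows later starts with higher p, lower q", {
  sens <- suppressWarnings(
    bass_sensitivity(hints_series(), c(2001, 2004, 2007))
  )
  tab <- sens$table
  expect_identical(nrow(tab), 3L)
  expect_true(all(diff(tab$q) < 0))    # q falls as the start moves later
  expect_true(all(diff(tab$p) > 0))    # p rises as the start moves later
  expect_true(all(diff(tab$q_over_p) < 0))
  # ratio column is definitionally q/p of each row's parameters
  for (f in Filter(function(x) inherits(x, "bass_fit"), sens$fits)) {
    expect_equal(f$q_over_p, motivation_ratio(f$params))
  }
  # single start year is identical to one direct fit
  one <- bass_sensitivity(hints_series(), 2001)
  direct <- bass_fit(hints_series(), 2001)
  one$fits[[1]]$call <- direct$call <- NULL
  expect_identical(unclass(one$fits[[1]])[names(unclass(direct))],
                   unclass(direct))
  # a failing row does not abort the others
  mixed <- suppressWarnings(bass_sensitivity(hints_series(), c(2009, 2001)))
  expect_true(inherits(mixed$fits[["2009"]], "condition"))
  expect_s3_class(mixed$fits[["2001"]], "bass_fit")
  expect_false(is.na(mixed$table$p[2]))
})

test_that("stability check recovers truth exactly on noise-free curves", {
  truth <- bass_params(0.005, 0.25, 1, 2004)
  ser <- data.frame(year = c(2008, 2011, 2013),
                    fraction = bass_cdf(truth, c(4, 7, 9)))
  st <- bass_stability(ser, 2004, 2020)
  expect_lt(st$abs_difference, 1e-6)
  # invariant to the presentation order of the input points
  st_shuffled <- bass_stability(ser[c(3, 1, 2), ], 2004, 2020)
  expect_equal(st$abs_difference, st_shuffled$abs_difference)
  expect_error(bass_stability(ser[1:2, ], 2004, 2020), "at least 3")
})

test_that("stability refit of the observed series is an exact interpolant", {
  # dropping 2013 leaves an exactly identified system; the refit must
  # interpolate the remaining two observations (zero residuals), which is
  # what makes the two-point forecast swing wide
  st <- bass_stability(hints_series(), 2004, 2020)
  expect_lt(max(abs(st$fit_reduced$residuals)), 1e-8)
  expect_identical(nrow(st$fit_reduced$series), 2L)
  expect_gt(st$abs_difference, 0)
})

test_that("policy-target fits produce the low-p, high-ratio policy curve", {
  mu <- fit_policy_targets()
  obs2004 <- bass_fit(hints_series(), start_year = 2004)
  expect_identical(mu$label, "MU targets")
  expect_true(mu$feasible)
  expect_lt(coef(mu)["p"], coef(obs2004)["p"])
  expect_gt(mu$q_over_p, obs2004$q_over_p)
  # targets on an exact Bass curve are recovered exactly
  truth <- bass_params(0.003, 0.2, 1, 2004)
  tgt <- data.frame(year = c(2014, 2017), fraction = bass_cdf(truth, c(10, 13)))
  fit <- fit_policy_targets(adoption_series(tgt), start_year = 2004)
  expect_lt(abs(coef(fit)["p"] - 0.003), 1e-6)
  expect_lt(abs(coef(fit)["q"] - 0.2), 1e-6)
})

test_that("infeasible data are flagged rather than silently accepted", {
  # a series no Bass curve can thread within a razor-thin band
  ser <- data.frame(year = c(2008, 2009, 2010, 2011),
                    fraction = c(0.05, 0.30, 0.31, 0.32))
  expect_warning(fit <- bass_fit(ser, 2001, band = 1e-6), "band|residuals")
  expect_false(fit$feasible)
})
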