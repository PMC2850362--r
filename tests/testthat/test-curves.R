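test_that("crossing_time matches the closed form for exponential growth", {
  # od_corr = 0.01 * 2^(t/2); reaches 0.32 at t = 2*log2(32) = 10 h
  cv <- exp_curve(delta = 2, od0 = 0.01)
  expect_equal(crossing_time(cv, 0.32), 10, tolerance = 1e-12)
  # off-grid level still exact under log2 interpolation
  expect_equal(crossing_time(cv, 0.3), 2 * log2(0.3 / 0.01),
               tolerance = 1e-9)
})

test_that("crossing_time handles boundary and dead-curve cases", {
  cv <- od_curve(0:10, rep(0.5, 11))
  expect_equal(crossing_time(cv, 0.3), 0)  # already above at t = 0
  blank <- od_curve(0:10, rep(0, 11))      # floored at epsilon
  expect_true(is.na(crossing_time(blank, 0.3)))
  expect_error(crossing_time(blank, 1e-5), "epsilon")
})

test_that("crossing_time is non-decreasing in level for monotone curves", {
  cv <- exp_curve(delta = 1.5)
  levels <- seq(0.05, 1.5, by = 0.05)
  ct <- vapply(levels, function(l) crossing_time(cv, l), 0)
  expect_true(all(diff(ct) >= 0))
})

test_that("both doubling-time estimators are exact on pure exponentials", {
  p <- curve_params()
  for (delta in c(0.8, 1.5, 3.2)) {
    cv <- exp_curve(delta, od0 = 0.05)
    expect_equal(doubling_time_inflection(cv, p), delta,
                 tolerance = 1e-9)
    expect_equal(doubling_time_interval(cv, p), delta,
                 tolerance = 1e-9)
  }
})

test_that("doubling-time estimators return NA on non-growing curves", {
  p <- curve_params()
  falling <- od_curve(0:10, 0.6 * 2^(-(0:10) / 2))
  expect_true(is.na(doubling_time_inflection(falling, p)))
  expect_true(is.na(doubling_time_interval(falling, p)))
  blank <- od_curve(0:10, rep(0.05, 11))
  expect_true(is.na(doubling_time_inflection(blank, p)))
  expect_true(is.na(doubling_time_interval(blank, p)))
})

test_that("estimators recover the exponential-phase rate of a logistic", {
  spec <- sim_spec(doubling_time = 2, noise_sd = 0)
  cv <- simulate_curve(spec, 1)
  p <- curve_params()
  expect_equal(doubling_time_inflection(cv, p), 2, tolerance = 0.05)
  expect_equal(doubling_time_interval(cv, p), 2, tolerance = 0.05)
})

test_that("the interval method beats inflection under OD noise on average", {
  # same noisy curves, both estimators; mean |error| compared over seeds
  spec <- sim_spec(doubling_time = 1.5, noise_sd = 0.005)
  p <- curve_params()
  errs <- vapply(1:100, function(s) {
    cv <- simulate_curve(spec, 1, seed = s)
    c(abs(doubling_time_interval(cv, p) - 1.5),
      abs(doubling_time_inflection(cv, p) - 1.5))
  }, numeric(2))
  expect_lt(mean(errs[1, ]), mean(errs[2, ]))
})

test_that("doubling times are scale-equivariant", {
  cv <- simulate_curve(sim_spec(noise_sd = 0.003), 1)
  p <- curve_params()
  for (c_scale in c(0.5, 3)) {
    cv2 <- od_curve(cv$times, cv$od_corr * c_scale)
    p2 <- curve_params(od_min = p$od_min * c_scale,
                       od_max = p$od_max * c_scale,
                       timeshift_od = p$timeshift_od * c_scale)
    expect_equal(doubling_time_inflection(cv2, p2),
                 doubling_time_inflection(cv, p), tolerance = 1e-9)
    expect_equal(doubling_time_interval(cv2, p2),
                 doubling_time_interval(cv, p), tolerance = 1e-9)
  }
})

test_that("time translation shifts crossings but not doubling times", {
  cv <- exp_curve(1.5, od0 = 0.02)
  p <- curve_params()
  shift <- 3.25
  cv2 <- od_curve(cv$times + shift, cv$od_raw)
  expect_equal(doubling_time_interval(cv2, p),
               doubling_time_interval(cv, p), tolerance = 1e-12)
  expect_equal(doubling_time_inflection(cv2, p),
               doubling_time_inflection(cv, p), tolerance = 1e-12)
  expect_equal(crossing_time(cv2, 0.3), crossing_time(cv, 0.3) + shift,
               tolerance = 1e-9)
})

test_that("the affine doubling-time correction applies and validates", {
  expect_equal(apply_dt_correction(2, c(1, 0)), 2)
  expect_equal(apply_dt_correction(2, c(0.9, 0.1)), 1.9)
  expect_error(apply_dt_correction(2, c(0, -1)), "not positive")
  expect_true(is.na(apply_dt_correction(NA_real_)))
})

test_that("curve_params validates threshold orderings", {
  expect_error(curve_params(od_min = 0.5, od_max = 0.2), "od_min")
  expect_error(curve_params(timeshift_od = 0), "positive")
  expect_error(curve_params(correction = 1), "two finite")
  expect_identical(curve_params()$dt_method, "interval")
})
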