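test_that("time_shift measures constructed delays exactly", {
  ref <- exp_curve(1.5, od0 = 0.01)
  expect_equal(time_shift(ref, ref, 0.3), 0)
  # same curve delayed by exactly 3 h: od0 scaled by 2^(-3/delta)
  delayed <- exp_curve(1.5, od0 = 0.01 * 2^(-3 / 1.5))
  expect_equal(time_shift(delayed, ref, 0.3), 3, tolerance = 1e-9)
  # dead culture
  flat <- od_curve(ref$times, rep(0, length(ref$times)))
  expect_true(is.na(time_shift(flat, ref, 0.3)))
  # failed reference is an error, not a value
  expect_error(time_shift(ref, flat, 0.3), "reference outgrowth failed")
})

test_that("survival_fraction halves per doubling time of delay", {
  expect_equal(survival_fraction(0, 2), 1)
  expect_equal(survival_fraction(2, 2), 0.5)
  for (k in 0:5) expect_equal(survival_fraction(k * 1.7, 1.7), 2^(-k))
  expect_equal(survival_fraction(3, 2), 2^(-1.5))
  expect_equal(survival_fraction(NA_real_, 2), 0)   # dead culture
  expect_gt(survival_fraction(-1, 2), 1)            # negative shift
  expect_error(survival_fraction(1, 0), "positive")
  expect_error(survival_fraction(1, NA), "positive")
})

test_that("clean_survival pins the reference at 1 and removes increases", {
  expect_equal(clean_survival(c(1.0, 0.8, 0.9, 0.4)), c(1, 0.8, 0.8, 0.4))
  # terminal gasping spike flattened
  expect_equal(clean_survival(c(1.0, 0.5, 0.2, 0.6)), c(1, 0.5, 0.2, 0.2))
  # raw reference above 1 (negative shift) is capped
  expect_equal(clean_survival(c(1.2, 0.9)), c(1, 0.9))
  expect_error(clean_survival(numeric(0)), "empty")
})

test_that("clean_survival output is monotone, bounded and idempotent", {
  set.seed(3)
  for (i in 1:50) {
    raw <- c(1, exp(rnorm(9, -1, 1)))
    cl <- clean_survival(raw)
    expect_equal(cl[1], 1)
    expect_true(all(diff(cl) <= 0))
    expect_true(all(cl >= 0 & cl <= 1))
    expect_equal(clean_survival(cl), cl)
  }
})

test_that("survival_integral is the day-weighted trapezoid", {
  expect_equal(survival_integral(c(2, 4, 6), c(1, 0.5, 0.25)), 2.25)
  expect_equal(survival_integral(c(0, 10), c(1, 1)), 10)
  expect_equal(survival_integral(c(2, 4, 9), c(1, 1, 1)), 7)
  expect_error(survival_integral(2, 1), "at least 2")
  expect_error(survival_integral(c(2, 2), c(1, 1)), "strictly increasing")
})

test_that("survival_integral is monotone in the survival curve", {
  set.seed(5)
  for (i in 1:20) {
    days <- cumsum(runif(6, 1, 3))
    lo <- clean_survival(c(1, runif(5)))
    hi <- pmin(1, lo + runif(6, 0, 0.2)); hi[1] <- 1
    expect_gte(survival_integral(days, hi), survival_integral(days, lo))
  }
})

test_that("build_lineages on identical runs gives unit survival", {
  fx <- make_exact_runs(days = c(2, 9), fractions_by_group =
                          list(WT = c(1, 1)))
  ln <- build_lineages(fx$runs, fx$wells)
  expect_equal(ln$ages$survival_clean, rep(1, 6))
  expect_equal(ln$wells$survival_integral, rep(7, 3))  # day span 9 - 2
})

test_that("build_lineages recovers programmed viabilities from exact curves", {
  fx <- make_exact_runs(days = c(2, 5, 8),
                        fractions_by_group = list(WT = c(1, 0.5, 0.1)),
                        delta = 1.5)
  ln <- build_lineages(fx$runs, fx$wells)
  for (pos in 1:3) {
    a <- ln$ages[ln$ages$position == pos, ]
    expect_equal(a$survival_clean, c(1, 0.5, 0.1), tolerance = 0.01)
  }
  expect_equal(ln$wells$ref_doubling_time, rep(1.5, 3), tolerance = 1e-9)
})

test_that("a well dead from the second age-point scores (1, 0, 0)", {
  fx <- make_exact_runs(days = c(2, 4, 6),
                        fractions_by_group = list(WT = c(1, 0, 0)),
                        n_rep = 1)
  ln <- build_lineages(fx$runs, fx$wells)
  expect_equal(ln$ages$survival_clean, c(1, 0, 0))
  expect_true(is.na(ln$ages$time_shift[2]))
  expect_equal(ln$wells$survival_integral, 1)  # trapezoid of (1,0,0) on 2,4,6
})

test_that("build_lineages validates run compatibility", {
  fx <- make_exact_runs(days = c(2, 4), fractions_by_group =
                          list(WT = c(1, 1)))
  expect_error(build_lineages(fx$runs[1], fx$wells), "at least 2")
  bad <- fx$runs
  bad[[2]]$day <- 2
  expect_error(build_lineages(bad, fx$wells), "unique")
})

test_that("errors inside a lineage are tagged with well and day", {
  # well 1's reference curve never grows -> reference failure at day 2
  times <- seq(0, 24, by = 0.5)
  flat <- rep(0.15, length(times))
  grow <- 0.15 + 0.01 * 2^(times / 1.5)
  runs <- lapply(c(2, 4), function(d) {
    wells <- cbind(w1 = flat, w2 = grow)
    outgrowth_run(raw_run_table(times, wells, sprintf("day%g", d)),
                  day = d, background = 0.15)
  })
  expect_error(build_lineages(runs, NULL), "well 1")
})
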