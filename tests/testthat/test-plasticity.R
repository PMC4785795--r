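const_series <- function(value, pathway = "test", n_min = 35, ind_min = 5) {
  epsc_series(seq(10, n_min * 60, by = 10), rep(value, n_min * 6),
              pathway = pathway, induction_time_s = ind_min * 60)
}

test_that("series-resistance QC applies the 20 % rule with a strict boundary", {
  mk <- function(rs) epsc_series(1:10, rep(30, 10), "test", 50,
                                 series_resistance_mohm = rs)
  expect_true(qc_series_resistance(mk(rep(15, 10))))
  expect_false(qc_series_resistance(mk(c(rep(15, 9), 15 * 1.25))))
  expect_true(qc_series_resistance(mk(c(rep(15, 9), 15 * 1.199))))
  expect_warning(ok <- qc_series_resistance(const_series(30)), "no resistance")
  expect_true(ok)
  expect_false(qc_series_resistance(const_series(30), on_missing = "fail"))
})

test_that("minute averaging groups six sweeps and drops partial groups", {
  s12 <- epsc_series(seq(10, 120, by = 10), rep(30, 12), "test", 600)
  m12 <- minute_average(s12)
  expect_length(m12$amplitudes_pa, 2)
  expect_true(all(m12$amplitudes_pa == 30))

  ramp <- epsc_series(seq(10, 120, by = 10), 1:12, "test", 600)
  expect_equal(minute_average(ramp)$amplitudes_pa, c(3.5, 9.5))

  s13 <- epsc_series(seq(10, 130, by = 10), 1:13, "test", 600)
  expect_length(minute_average(s13)$amplitudes_pa, 2)

  expect_error(minute_average(epsc_series(1:5, 1:5, "test", 600)), "fewer")
})

test_that("baseline normalization divides by the pre-induction mean", {
  flat <- normalize_to_baseline(const_series(30))
  expect_true(all(flat$amplitudes_pa == 1))

  step <- epsc_series(seq(10, 1800, by = 10),
                      c(rep(30, 30), rep(60, 150)), "test", 300)
  ns <- normalize_to_baseline(step)
  expect_true(all(ns$amplitudes_pa[31:180] == 2))
  expect_equal(mean(ns$amplitudes_pa[1:30]), 1)

  zero <- epsc_series(seq(10, 1800, by = 10), rep(0, 180), "test", 300)
  expect_error(normalize_to_baseline(zero), "zero baseline")
  expect_error(normalize_to_baseline(const_series(30)[["amplitudes_pa"]]),
               class = "simpleError")
})

test_that("pathway comparison reproduces hand-computed relative change", {
  # identical pathways: zero change, p = 1
  same <- compare_pathways(
    lapply(1:4, function(i) const_series(1, "test")),
    lapply(1:4, function(i) const_series(1, "control"))
  )
  expect_equal(same$relative_change, 0)
  expect_equal(same$p_value, 1)

  # constant windows at 3.36 and 1.28 -> relative change 2.08
  out <- compare_pathways(
    lapply(1:8, function(i) const_series(3.36, "test")),
    lapply(1:8, function(i) const_series(1.28, "control"))
  )
  expect_equal(out$norm_test_final, 3.36)
  expect_equal(out$norm_control_final, 1.28)
  expect_equal(out$relative_change, 2.08)
  expect_equal(out$n, 8)

  expect_error(
    compare_pathways(list(const_series(1)), list(const_series(1), const_series(1))),
    "unequal"
  )
})

test_that("a planted factor-2 LTP is detected in most replicate experiments", {
  # Monte-Carlo power check: n = 8 experiments, factor 2 vs 1, cv 0.1
  hits <- vapply(1:200, function(rep) {
    test <- lapply(1:8, function(i) {
      normalize_to_baseline(minute_average(
        gen_epsc_series(true_factor = 2, noise_cv = 0.1, seed = rep * 100 + i)
      ))
    })
    ctrl <- lapply(1:8, function(i) {
      normalize_to_baseline(minute_average(
        gen_epsc_series(true_factor = 1, noise_cv = 0.1, seed = rep * 100 + 50 + i)
      ))
    })
    compare_pathways(test, ctrl)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("predictor correlation reports OLS r-squared with its invariances", {
  perfect <- correlate_predictor(0.25 * c(0, 2, 4, 8), c(0, 2, 4, 8))
  expect_equal(perfect$r_squared, 1)

  set.seed(99)
  x <- 0:7
  y <- 0.3 * x + rnorm(8, sd = 0.1)
  f <- correlate_predictor(y, x)
  # affine transforms of either variable leave r^2 unchanged
  f2 <- correlate_predictor(3 * y - 7, x)
  f3 <- correlate_predictor(y, -2 * x + 5)
  expect_equal(f2$r_squared, f$r_squared)
  expect_equal(f3$r_squared, f$r_squared)

  expect_error(correlate_predictor(c(1, 2), c(1, 2)), "at least 3")
  expect_error(correlate_predictor(c(1, 2, 3), c(2, 2, 2)), "zero variance")
})

test_that("normalization commutes with amplitude rescaling", {
  ser <- gen_epsc_series(true_factor = 1.8, noise_cv = 0.15, seed = 12)
  scaled <- epsc_series(ser$sweep_times_s, 7.3 * ser$amplitudes_pa,
                        pathway = ser$pathway,
                        induction_time_s = ser$induction_time_s)
  a <- normalize_to_baseline(minute_average(ser))
  b <- normalize_to_baseline(minute_average(scaled))
  expect_equal(a$amplitudes_pa, b$amplitudes_pa, tolerance = 1e-12)
})
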