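test_that("nearest-rank threshold separates exactly the bottom 1%", {
  # 100 trajectories with distinct peaks 1..100
  P <- cbind(1:100, 0)
  ens <- fake_ensemble(P)
  th <- define_threshold(ens)
  expect_equal(th$theta_peak, 2) # smallest peak of the top 99%
  expect_identical(th$n_fail, 1L)
  expect_identical(th$fail_index, 1L)
  expect_equal(th$self_raw_failure, 1)
  expect_equal(sum(peak_levels(ens) < th$theta_peak), 1L)
  expect_error(define_threshold(fake_ensemble(cbind(1:50, 0))),
               "at least 100")
})

test_that("degenerate and zero ensembles are handled", {
  zeros <- fake_ensemble(matrix(0, 100, 3))
  expect_warning(th <- define_threshold(zeros), "degenerate")
  expect_equal(th$theta_peak, 0)
  expect_true(th$degenerate)
  # theta_t = 0 everywhere -> E(t) = 0 (nothing is strictly below 0)
  E <- underexpression_series(zeros, th)
  expect_equal(unname(E), rep(0, 3))
})

test_that("under-expression series follows the strict-below rule", {
  full <- fake_ensemble(matrix(rep(1:100, 3), 100, 3))
  suppressWarnings(th <- define_threshold(full))
  dead <- fake_ensemble(matrix(0, 100, 3))
  expect_equal(unname(underexpression_series(dead, th)), rep(1, 3))
  expect_error(
    underexpression_series(fake_ensemble(matrix(0, 100, 5)), th),
    "grid")
})

test_that("identical full and partial ensembles give the 1% raw floor", {
  P <- cbind(1:200, 0)
  ens <- fake_ensemble(P)
  ef <- error_frequency(ens, ens)
  expect_equal(ef$raw_failure, 1)
  expect_equal(ef$error_frequency, 0)
  # partial identically zero against a positive threshold
  dead <- fake_ensemble(matrix(0, 200, 2))
  ef0 <- error_frequency(dead, ens)
  expect_equal(ef0$raw_failure, 100)
  expect_equal(ef0$error_frequency, 99)
})

test_that("commitment time implements the 30% rising-phase rule", {
  ramp <- list(grid = 0:10, mean = seq(0, 1, by = 0.1))
  expect_equal(commitment_time(ramp), 3)
  # invariant to positive rescaling of the mean
  expect_equal(commitment_time(list(grid = 0:10,
                                    mean = 5 * seq(0, 1, by = 0.1))), 3)
  # constant at max from the start -> first grid point
  expect_equal(commitment_time(list(grid = 0:10, mean = rep(2, 11))), 0)
  expect_error(commitment_time(list(grid = 0:10, mean = rep(0, 11))),
               "zero")
})

test_that("mean under-expression averages E(t) by the trapezoid rule", {
  grid <- seq(0, 10, length.out = 101)
  expect_equal(mean_underexpression(rep(0, 101), grid, 0, 10), 0)
  expect_equal(mean_underexpression(rep(1, 101), grid, 0, 10), 1)
  # E(t) = t / tau -> analytic mean 1/2 (trapezoid exact on a line)
  expect_equal(mean_underexpression(grid / 10, grid, 0, 10), 0.5)
  # tau = onset degenerates to the pointwise value
  expect_equal(mean_underexpression(grid / 10, grid, 5, 5), 0.5)
  expect_error(mean_underexpression(grid / 10, grid, 5, 4), "onset")
})

test_that("raw failure is monotone in severity", {
  p <- default_rate_params()
  inp <- step_input()
  part <- simulate_ensemble(
    "linear", apply_activation(p, activation_scheme("partial")),
    inp, n = 800, seed = 51)
  raws <- vapply(c(0.25, 1, 4), function(s) {
    full <- simulate_ensemble(
      "linear",
      apply_activation(p, activation_scheme("full", "transcript", s)),
      inp, n = 800, seed = 50)
    error_frequency(part, full)$raw_failure
  }, numeric(1))
  expect_true(all(diff(raws) > 0))
})

test_that("severity calibration is deterministic and hits its target", {
  p <- default_rate_params()
  inp <- step_input()
  cal1 <- calibrate_severity("linear", p, inp, stage = "transcript",
                             n = 1000L, seed = 3, tol = 0.03)
  cal2 <- calibrate_severity("linear", p, inp, stage = "transcript",
                             n = 1000L, seed = 3, tol = 0.03)
  expect_identical(cal1$severity, cal2$severity)
  expect_identical(cal1$achieved_raw_failure, cal2$achieved_raw_failure)
  expect_lte(abs(cal1$achieved_raw_failure - 0.60), 0.03)
  expect_error(
    calibrate_severity("linear", p, inp, target_raw_failure = 0.005),
    "target_raw_failure")
})

test_that("error reports bundle consistent in-range statistics", {
  p <- default_rate_params()
  inp <- step_input()
  full <- simulate_ensemble(
    "linear",
    apply_activation(p, activation_scheme("full", "transcript", 1)),
    inp, n = 600, seed = 71)
  part <- simulate_ensemble(
    "linear", apply_activation(p, activation_scheme("partial")),
    inp, n = 600, seed = 72)
  er <- error_report(part, full)
  expect_true(all(er$E_series >= 0 & er$E_series <= 1))
  expect_gte(er$mean_underexpression, 0)
  expect_lte(er$mean_underexpression, 1)
  expect_gte(er$tau, inp$onset)
  expect_equal(er$error_frequency, er$raw_failure - 1)
})
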