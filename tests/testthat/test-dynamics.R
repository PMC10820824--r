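test_that("normalization divides by the reference and drops bad cells", {
  cells <- data.frame(reporter_mean = c(50, 30, 10),
                      reference_mean = c(100, 60, 0))
  expect_message(out <- normalize_expression(cells), "1 cell")
  expect_equal(nrow(out), 2L)
  expect_equal(out$expression, c(0.5, 0.5))
})

test_that("the furrow clock converts position to developmental time", {
  disk <- make_disk(r8_spacing = 100, noise_sd = 0, seed = 2)
  timed <- furrow_clock(disk, hours_per_column = 2)
  expect_equal(attr(timed, "column_spacing"), 100, tolerance = 1e-9)
  expect_equal(attr(timed, "conversion_factor"), 0.02)
  # x = 500 px -> 10 h
  i <- which.min(abs(timed$x_px - 500))
  expect_equal(timed$time[i], timed$x_px[i] * 0.02)
  # rescaling the pixel units leaves developmental time invariant,
  # because the column-spacing ruler rescales with it
  disk2 <- disk
  disk2$x_px <- 2 * disk2$x_px
  timed2 <- furrow_clock(disk2)
  expect_equal(timed2$time, timed$time, tolerance = 1e-9)
  expect_equal(attr(timed2, "conversion_factor"), 0.01)
  expect_error(furrow_clock(disk[disk$cell_type == "progenitor", ]),
               "fewer than 3 R8")
})

test_that("the moving average is exact on linear series", {
  t <- sort(runif(400, 0, 20))
  y <- 3 * t - 5
  sm <- moving_average(t, y, window = 100)
  expect_equal(sm$mean, y, tolerance = 1e-8)
  # constant series pass through and short series warn
  smc <- moving_average(1:300, rep(2, 300))
  expect_equal(smc$mean, rep(2, 300))
  expect_warning(sh <- moving_average(1:20, rnorm(20), window = 250),
                 "shorter than the window")
  expect_true(attr(sh, "short_series"))
  expect_error(moving_average(c(2, 1), c(0, 0)), "sorted")
})

test_that("smoothing reduces noise variance on a known trend", {
  set.seed(8)
  t <- sort(runif(1500, 0, 30))
  signal <- sin(t / 5)
  y <- signal + rnorm(1500, sd = 0.5)
  sm <- moving_average(t, y, window = 250)
  expect_lt(mean((sm$mean - signal)^2), 0.1 * mean((y - signal)^2))
})

test_that("bootstrap bands behave on degenerate and noisy input", {
  t <- 1:300
  band0 <- bootstrap_band(t, rep(1.5, 300), n_boot = 100, seed = 1)
  expect_equal(band0$lo, rep(1.5, 300))
  expect_equal(band0$hi, rep(1.5, 300))
  set.seed(5)
  y <- rnorm(300, 2, 0.3)
  band <- bootstrap_band(t, y, window = 100, n_boot = 400, seed = 2)
  sm <- moving_average(t, y, window = 100, secondary = FALSE)
  expect_true(all(band$lo <= band$hi))
  inside <- mean(sm$mean >= band$lo & sm$mean <= band$hi)
  expect_gt(inside, 0.8)
})

test_that("cross-correlation alignment recovers injected shifts", {
  t <- seq(0, 40, by = 0.05)
  f <- function(s) exp(-((s - 15) / 6)^2)
  self <- align_pair(t, f(t), t, f(t))
  expect_equal(self$dt, 0)
  # affine level scaling leaves the optimum unchanged
  aff <- align_pair(t, 7 * f(t) + 3, t, f(t))
  expect_equal(aff$dt, 0)
  # injected 4 h delay recovered to the lag resolution
  sh <- align_pair(t, f(t - 4), t, f(t))
  expect_lt(abs(sh$dt - 4), sh$lag_step + 1e-9)
  expect_error(align_pair(t, rep(1, length(t)), t, f(t)),
               "zero-variance")
})

test_that("experiment alignment recovers replicate time offsets", {
  d1 <- make_disk(noise_sd = 0.05, shift = 0, disk_id = "a", seed = 11)
  d2 <- make_disk(noise_sd = 0.05, shift = 3, disk_id = "b", seed = 12)
  cells <- normalize_expression(rbind(furrow_clock(d1),
                                      furrow_clock(d2)))
  al <- align_experiment(cells, seed = 1, rebase_offset = 10)
  ref <- al$shifts$disk_id[al$shifts$role == "reference"]
  # end-to-end invariant: after alignment, cells at the same true
  # developmental stage sit at the same aligned time in both disks.
  # True stage is x * hours_per_column / r8_spacing plus the injected
  # 3 h shift of disk b.
  ca <- al$cells[al$cells$disk_id == "a", ]
  cb <- al$cells[al$cells$disk_id == "b", ]
  off_a <- mean(ca$time - ca$x_px * 2 / 40)
  off_b <- mean(cb$time - (cb$x_px * 2 / 40 + 3))
  expect_lt(abs(off_a - off_b), 1)
  # reference rebasing: time zero at its first R8, then +10 h display
  ref_r8 <- al$cells$time[al$cells$disk_id == ref &
                          al$cells$cell_type == "R8"]
  expect_equal(min(ref_r8), 10, tolerance = 1e-9)
  # single-disk experiments only rebase
  single <- align_experiment(cells[cells$disk_id == "a", ], seed = 1)
  expect_equal(nrow(single$shifts), 1L)
  expect_equal(single$shifts$role, "reference")
})
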