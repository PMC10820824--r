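test_that("halton sequence reproduces the radical-inverse values", {
  u <- halton_sequence(6, 2)
  expect_equal(u[, 1], c(1/2, 1/4, 3/4, 1/8, 5/8, 3/8))
  expect_equal(u[, 2], c(1/3, 2/3, 1/9, 4/9, 7/9, 2/9))
  s1 <- halton_sequence(50, 7, seed = 5)
  s2 <- halton_sequence(50, 7, seed = 5)
  expect_identical(s1, s2)
  s3 <- halton_sequence(50, 7, seed = 6)
  expect_false(identical(s1, s3))
  expect_true(all(s1 >= 0 & s1 < 1))
  expect_error(halton_sequence(10, 26), "dim")
})

test_that("parameter sets respect the tenfold log-uniform bounds", {
  d <- default_rate_params()
  sets <- sample_parameter_sets(n = 1000, seed = 2)
  for (nm in c("k_G", "gamma_G", "k_R", "gamma_R", "k_P", "gamma_P")) {
    ctr <- d[[nm]]
    expect_true(all(sets[[nm]] >= ctr / sqrt(10) - 1e-12))
    expect_true(all(sets[[nm]] <= ctr * sqrt(10) + 1e-12))
    # log-marginal is uniform on its range
    z <- (log(sets[[nm]]) - log(ctr / sqrt(10))) / log(10)
    ks <- suppressWarnings(ks.test(z, "punif"))
    expect_gt(ks$p.value, 0.05)
  }
  # span = 1 collapses every draw to the center
  fixed <- sample_parameter_sets(n = 10, span = 1, seed = 2)
  expect_equal(unique(fixed$k_R), d$k_R)
  expect_error(sample_parameter_sets(n = 10, span = 0.5), "span")
})

test_that("zero severity makes full and partial activation equivalent", {
  sets <- sample_parameter_sets(n = 1, span = 1, severity = 1, seed = 1)
  sets$severity <- 0
  sw <- run_sweep(sets, "linear", ensemble_n = 1000,
                  conditions = "normal", seed = 11)
  rec <- sw$records
  expect_identical(rec$status, "ok")
  # partial vs full differ only by Monte-Carlo error -> |ef| small
  expect_lt(abs(rec$error_frequency), 2)
})

test_that("a sweep is resumable with byte-identical records", {
  sets <- sample_parameter_sets(n = 4, seed = 3)
  d1 <- file.path(tempdir(), "sw1")
  sw1 <- run_sweep(sets, "linear", ensemble_n = 200,
                   conditions = c("normal", "reduced"), seed = 7,
                   out_dir = d1)
  # delete half the records and rerun: skipped + recomputed must agree
  files <- list.files(d1, full.names = TRUE)
  kept <- readLines(files[2])
  file.remove(files[c(1, 3)])
  sw2 <- run_sweep(sets, "linear", ensemble_n = 200,
                   conditions = c("normal", "reduced"), seed = 7,
                   out_dir = d1)
  expect_identical(readLines(files[2]), kept)
  expect_equal(sw1$records, sw2$records)
  unlink(d1, recursive = TRUE)
})

test_that("condense_projection matches a brute-force computation", {
  rec <- data.frame(
    id = rep(1:3, each = 2),
    condition = rep(c("normal", "reduced"), 3),
    raw_failure = 1:6,
    error_frequency = c(1, 4, 2, 7, 3, 5),
    mean_underexpression = 0.1, status = "ok")
  sw <- structure(list(records = rec,
                       conditions = c("normal", "reduced"),
                       variant = "linear", ensemble_n = 0, seed = 1),
                  class = "sweep_result")
  cp <- condense_projection(sw, probs = 0.5)
  expect_equal(cp$differences$reduced_minus_normal, c(3, 5, 2))
  expect_equal(unname(cp$quantiles$reduced_minus_normal), 3)
  expect_equal(unname(cp$quantiles$normal), 2)
  expect_named(cp$histograms,
               c("normal", "reduced", "reduced_minus_normal"))
})
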