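test_that("zero input yields the identically zero trajectory", {
  p <- default_rate_params()
  null_input <- step_input(amplitude = 0, basal = 0)
  tr <- simulate_ssa("linear", p, null_input, horizon = 13, seed = 4)
  expect_equal(unique(tr$D), 0)
  expect_equal(unique(tr$R), 0)
  expect_equal(unique(tr$P), 0)
})

test_that("trajectories and ensembles are deterministic under the seed", {
  p <- default_rate_params()
  inp <- step_input()
  t1 <- simulate_ssa("linear", p, inp, seed = 9, stream = 2)
  t2 <- simulate_ssa("linear", p, inp, seed = 9, stream = 2)
  expect_identical(t1$time, t2$time)
  expect_identical(t1$P, t2$P)
  t3 <- simulate_ssa("linear", p, inp, seed = 9, stream = 3)
  expect_false(identical(t1$time, t3$time))

  e1 <- simulate_ensemble("linear", p, inp, n = 40, seed = 9)
  e2 <- simulate_ensemble("linear", p, inp, n = 40, seed = 9)
  expect_identical(e1$P, e2$P)
})

test_that("event-method ensemble rows replay as standalone trajectories", {
  p <- default_rate_params()
  inp <- step_input()
  ens <- simulate_ensemble("linear", p, inp, n = 5, seed = 31,
                           method = "event")
  for (i in c(1L, 3L, 5L)) {
    tr <- simulate_ssa("linear", p, inp, seed = 31, stream = i)
    expect_equal(unname(ens$P[i, ]),
                 eval_on_grid(tr$time, tr$P, ens$grid))
  }
})

test_that("states are non-negative integers and the bounded gene is conserved", {
  p <- default_rate_params()
  inp <- step_input()
  tr <- simulate_ssa("bounded", p, inp, seed = 6)
  expect_true(all(tr$D >= 0 & tr$D <= p$allele_bound)) # G_on + G_off = 2
  expect_true(all(tr$R >= 0 & tr$P >= 0))
  expect_true(all(tr$D == round(tr$D)))
  expect_true(all(tr$P == round(tr$P)))
  expect_true(all(diff(tr$time) > 0))
})

test_that("ensembles carry intrinsic noise and reject bad arguments", {
  p <- default_rate_params()
  inp <- step_input()
  ens <- simulate_ensemble("linear", p, inp, n = 300, seed = 2)
  pk <- peak_levels(ens)
  expect_gt(sd(pk) / mean(pk), 0)
  expect_error(simulate_ssa("linear", p, step_input(onset = 5), horizon = 4),
               "horizon")
  expect_error(simulate_ensemble("linear", p, inp, n = 0), "n >= 1")
})

test_that("conditional and event methods agree in distribution", {
  p <- default_rate_params()
  inp <- step_input()
  a <- simulate_ensemble("linear", p, inp, n = 2000, seed = 21)
  b <- simulate_ensemble("linear", p, inp, n = 2000, seed = 22,
                         method = "event")
  # grid-time means agree within Monte-Carlo error
  z <- (colMeans(a$P) - colMeans(b$P)) /
    sqrt(apply(a$P, 2, var) / 2000 + apply(b$P, 2, var) / 2000 + 1e-12)
  expect_lt(max(abs(z)), 4.5)
  # peak-level distributions agree
  ks <- suppressWarnings(ks.test(peak_levels(a), peak_levels(b)))
  expect_gt(ks$p.value, 0.01)
  for (v in c("bounded", "hill")) {
    av <- simulate_ensemble(v, p, inp, n = 1500, seed = 23)
    bv <- simulate_ensemble(v, p, inp, n = 1500, seed = 24,
                            method = "event")
    ksv <- suppressWarnings(ks.test(peak_levels(av), peak_levels(bv)))
    expect_gt(ksv$p.value, 0.01)
  }
})

test_that("internal Poisson and binomial samplers match the exact laws", {
  rp <- flypulse:::rpois_stream_cpp
  rb <- flypulse:::rbinom_stream_cpp
  # small-mean inversion branch and large-mean PTRS branch
  for (lam in c(0.5, 5, 50)) {
    x <- rp(5e4, lam, 7)
    hi <- ceiling(lam + 6 * sqrt(lam + 1))
    expect_gt(chisq_gof_p(x, function(k) dpois(k, lam), hi), 1e-3)
  }
  # BINV branch, BTRS branch, and the p > 0.5 flip
  for (cfg in list(c(5, 0.3), c(100, 0.05), c(1000, 0.2), c(100, 0.95))) {
    x <- rb(5e4, cfg[1], cfg[2], 13)
    expect_gt(chisq_gof_p(x, function(k) dbinom(k, cfg[1], cfg[2]),
                          cfg[1]), 1e-3)
  }
  expect_identical(unique(rp(100, 0, 1)), 0)
  expect_identical(unique(rb(100, 10, 0, 1)), 0)
  expect_identical(unique(rb(100, 10, 1, 1)), 10)
})
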