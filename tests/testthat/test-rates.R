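test_that("metabolic scaling multiplies exactly the ATP-dependent constants", {
  p <- rate_params(k_G = 1, gamma_G = 1, k_R = 2, gamma_R = 1,
                   k_P = 4, gamma_P = 0.1, eta_R = 1, eta_P = 2,
                   eta_G = 3)

  same <- scale_for_metabolism(p, "normal")
  expect_identical(unclass(same), unclass(p))

  red <- scale_for_metabolism(p, "reduced")
  expect_equal(red$k_R, 1)
  expect_equal(red$k_P, 2)
  expect_equal(red$gamma_P, 0.05)
  expect_equal(red$eta_R, 0.5)
  expect_equal(red$eta_P, 1)
  # not named as ATP-dependent: unchanged
  expect_equal(red$k_G, p$k_G)
  expect_equal(red$gamma_G, p$gamma_G)
  expect_equal(red$gamma_R, p$gamma_R)
  expect_equal(red$eta_G, p$eta_G)

  up <- scale_for_metabolism(p, "elevated")
  expect_equal(up$k_R, 3)

  # optional flags widen the scaled set
  red2 <- scale_for_metabolism(p, "reduced", scale_eta_G = TRUE,
                               scale_gamma_R = TRUE)
  expect_equal(red2$eta_G, 1.5)
  expect_equal(red2$gamma_R, 0.5)
})

test_that("metabolic scaling is multiplicative and invertible", {
  p <- default_rate_params()
  red <- scale_for_metabolism(p, "reduced")
  # the input is untouched
  expect_equal(p$k_R, 10)
  # halving twice equals quartering once; 2x undoes 0.5x exactly
  back <- scale_for_metabolism(red, metabolic_condition("reduced"))
  expect_equal(back$k_R, p$k_R / 4)
  undone <- unclass(red)
  for (nm in c("k_R", "k_P", "gamma_P", "eta_R", "eta_P"))
    undone[[nm]] <- undone[[nm]] * 2
  expect_equal(undone, unclass(p))
  expect_error(scale_for_metabolism(p, "fast"), "condition|arg")
})

test_that("activation schemes set and zero the auxiliary constants", {
  p <- default_rate_params()
  full <- apply_activation(p, activation_scheme("full", "transcript", 0.5))
  expect_equal(full$eta_R, 0.5 * p$k_R)
  expect_equal(full$eta_G, 0)
  expect_equal(full$eta_P, 0)

  all3 <- apply_activation(
    p, activation_scheme("full", c("gene", "transcript", "protein"), 2))
  expect_equal(all3$eta_G, 2 * p$k_G)
  expect_equal(all3$eta_R, 2 * p$k_R)
  expect_equal(all3$eta_P, 2 * p$k_P)

  # partial zeroes everything regardless of severity
  part <- apply_activation(all3, activation_scheme("partial"))
  expect_equal(c(part$eta_G, part$eta_R, part$eta_P), c(0, 0, 0))

  expect_error(activation_scheme("full", "ribosome"), "stage")
  expect_error(activation_scheme("full", "gene", -1), "severity")
})

test_that("rate parameter validation rejects invalid values", {
  expect_error(rate_params(k_G = -1, gamma_G = 1, k_R = 1, gamma_R = 1,
                           k_P = 1, gamma_P = 1), "non-negative")
  expect_error(rate_params(k_G = 1, gamma_G = 1, k_R = NA, gamma_R = 1,
                           k_P = 1, gamma_P = 1), "k_R")
  expect_error(rate_params(k_G = 1, gamma_G = 1, k_R = 1, gamma_R = 1,
                           k_P = 1, gamma_P = 1, allele_bound = 0),
               "allele_bound")
  # defaults are valid and carry the documented values
  d <- default_rate_params()
  expect_equal(unclass(d)[c("k_G", "gamma_G", "k_R", "gamma_R",
                            "k_P", "gamma_P")],
               list(k_G = 20, gamma_G = 10, k_R = 10, gamma_R = 1,
                    k_P = 10, gamma_P = 0.5))
  expect_equal(d$hill_half_max, 0.5)
  expect_identical(d$allele_bound, 2L)
})

test_that("stored default severities are available per stage", {
  for (st in c("gene", "transcript", "protein", "all")) {
    s <- default_severity(st)
    expect_true(is.numeric(s) && length(s) == 1L && s > 0)
  }
  expect_error(default_severity("ribosome"))
})
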