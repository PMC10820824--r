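test_that("triangulation builds edges, neighbors and hull correctly", {
  # right triangle: every pair is an edge, all points on the hull
  tri <- triangulate(data.frame(x = c(0, 1, 0), y = c(0, 0, 1)))
  expect_equal(tri$n, 3L)
  expect_equal(nrow(tri$edges), 3L)
  expect_equal(sort(tri$edges$length), c(1, 1, sqrt(2)))
  expect_setequal(tri$hull, 1:3)
  expect_error(triangulate(data.frame(x = c(0, 1), y = c(0, 0))),
               "3 points")
  expect_error(triangulate(data.frame(x = c(0, 0, 1), y = c(0, 0, 1))),
               "duplicate")
  expect_error(triangulate(data.frame(x = 0:4, y = 2 * (0:4))),
               "collinear")
})

test_that("hexagonal interior points have six equidistant neighbors", {
  hex <- make_hex_lattice(rows = 10, cols = 10, spacing = 20)
  lat <- triangulate(hex)
  analysis <- restrict_region(lat, radius = 60)
  expect_gt(length(analysis), 0)
  for (pt in analysis) {
    nb <- lat$neighbors[[pt]]
    expect_equal(length(nb), 6L)
    dd <- sqrt(rowSums((lat$points[nb, , drop = FALSE] -
                        matrix(lat$points[pt, ], length(nb), 2,
                               byrow = TRUE))^2))
    expect_equal(dd, rep(20, 6), tolerance = 1e-9)
  }
  # neighbor relation is symmetric
  for (pt in seq_len(lat$n))
    for (nb in lat$neighbors[[pt]])
      expect_true(pt %in% lat$neighbors[[nb]])
})

test_that("restrict_region equals the brute-force definition", {
  hex <- make_hex_lattice(rows = 30, cols = 30, spacing = 15,
                          jitter_sd = 1, seed = 4)
  lat <- triangulate(hex)
  keep <- restrict_region(lat, radius = 120)
  ctr <- colMeans(lat$points)
  d <- sqrt((lat$points[, 1] - ctr[1])^2 + (lat$points[, 2] - ctr[2])^2)
  brute <- setdiff(which(d <= 120), as.integer(chull(lat$points)))
  expect_setequal(keep, brute)
  expect_warning(restrict_region(lat, radius = 0.001), "empty")
})

test_that("a perfect lattice has zero disorder", {
  lat <- triangulate(make_hex_lattice(rows = 15, cols = 15, spacing = 10))
  rec <- disorder_metric(lat, restrict_region(lat, radius = 40))
  expect_lt(max(rec$D), 1e-12)
  expect_equal(attr(rec, "mean_distance"), 10, tolerance = 1e-9)
})

test_that("disorder is invariant under rigid motion and uniform scale", {
  hex <- make_hex_lattice(rows = 12, cols = 12, spacing = 18,
                          jitter_sd = 2, seed = 9)
  base <- triangulate(hex)
  d0 <- disorder_metric(base, restrict_region(base, radius = 70))$D
  th <- 0.7
  rot <- cbind(cos(th) * hex$x - sin(th) * hex$y + 41,
               sin(th) * hex$x + cos(th) * hex$y - 13)
  moved <- triangulate(data.frame(x = rot[, 1], y = rot[, 2]))
  d1 <- disorder_metric(moved, restrict_region(moved, radius = 70))$D
  expect_equal(sort(d1), sort(d0), tolerance = 1e-9)
  scl <- triangulate(data.frame(x = 3.7 * hex$x, y = 3.7 * hex$y))
  d2 <- disorder_metric(scl, restrict_region(scl, radius = 3.7 * 70))$D
  expect_equal(sort(d2), sort(d0), tolerance = 1e-9)
})

test_that("distance perturbation behaves as documented", {
  lat <- triangulate(make_hex_lattice(rows = 20, cols = 20, spacing = 20))
  same <- perturb_distances(lat, 0, seed = 5)
  expect_identical(same$edges$length, lat$edges$length)
  noisy <- perturb_distances(lat, 0.1, seed = 5)
  expect_identical(perturb_distances(lat, 0.1, seed = 5)$edges$length,
                   noisy$edges$length)
  rec <- disorder_metric(noisy, restrict_region(noisy, radius = 150))
  # expected mean range of 6 iid U(0.9, 1.1) draws: 0.2 * 5/7
  expect_equal(mean(rec$D), 0.2 * 5 / 7, tolerance = 0.03)
  expect_error(perturb_distances(lat, -0.1), "half_width")
})

test_that("lattice features are degenerate on a perfect lattice", {
  perfect <- triangulate(make_hex_lattice(rows = 10, cols = 10,
                                          spacing = 10))
  f <- lattice_features(perfect)
  # a finite staggered patch has sliver triangles (30-30-120) along the
  # zigzag boundary; the interior is equilateral, so 60 degrees and the
  # unit spacing dominate
  expect_true(all(unique(round(f$features$vertex_angle, 6)) %in%
                  c(30, 60, 120)))
  expect_gt(mean(abs(f$features$vertex_angle - 60) < 1e-6), 0.8)
  expect_equal(median(f$features$edge_length), 10)
  expect_equal(median(f$features$vertex_angle), 60)
  # dispersion grows monotonically with positional jitter
  cvs <- vapply(c(0, 0.5, 1.5), function(js) {
    l <- triangulate(make_hex_lattice(rows = 10, cols = 10, spacing = 10,
                                      jitter_sd = js, seed = 3))
    lattice_features(l)$dispersion$cv[1]
  }, numeric(1))
  expect_true(all(diff(cvs) > 0))
})

test_that("bootstrap of the mean disorder is consistent", {
  expect_error(bootstrap_mean(1), "at least 2")
  flat <- bootstrap_mean(rep(0.4, 50), n_boot = 200, seed = 1)
  expect_equal(flat$mean, 0.4)
  expect_equal(flat$sd, 0)
  set.seed(10)
  x <- rnorm(400, 1, 0.2)
  bd <- bootstrap_mean(x, n_boot = 4000, seed = 2)
  expect_equal(bd$mean, mean(x), tolerance = 0.01)
  # bootstrap SE matches the analytic standard error of the mean
  se <- sd(x) / sqrt(400)
  expect_lt(abs(bd$sd - se) / se, 0.15)
  expect_identical(bootstrap_mean(x, n_boot = 4000, seed = 2)$boot_means,
                   bd$boot_means)
})

test_that("centering for comparison preserves the difference of means", {
  a <- bootstrap_mean(rnorm(50, 2), seed = 3, n_boot = 500)
  b <- bootstrap_mean(rnorm(50, 5), seed = 4, n_boot = 500)
  cc <- center_for_comparison(a, b)
  expect_equal(cc$reference$mean, 0)
  expect_equal(cc$other$mean - cc$reference$mean, b$mean - a$mean)
  # idempotent: re-centering shifts nothing further
  cc2 <- center_for_comparison(cc$reference, cc$other)
  expect_equal(cc2$other$boot_means, cc$other$boot_means)
  expect_equal(cc2$reference$offset, cc$reference$offset)
})
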