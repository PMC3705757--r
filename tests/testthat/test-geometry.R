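test_that("geometry construction follows the scan protocol", {
  g <- ct_geometry(128, oversampling = 2)
  expect_equal(g$n_views, 128L)
  expect_equal(g$bin_spacing, 0.5)
  expect_equal(g$fine_ray_step, 0.25)
  ## detector covers the image diagonal
  expect_gte(g$n_bins, ceiling(sqrt(2) * 128 / g$bin_spacing))
  ## measurement matrix has ~2.82 n^2 elements
  expect_equal(g$n_views * g$n_bins / 128^2, 2 * sqrt(2), tolerance = 0.02)
  ## evenly spaced angles in [0, pi)
  g8 <- ct_geometry(8, oversampling = 1)
  expect_equal(g8$angles, (0:7) * pi / 8)
  expect_error(ct_geometry(4), "degenerate")
})

test_that("Radon transform and back projection are exact adjoints and linear", {
  g <- test_geom(16)
  set.seed(42)
  for (rep in 1:3) {
    f <- matrix(runif(16^2), 16)
    s <- matrix(runif(g$n_views * g$n_bins), g$n_views)
    lhs <- sum(radon_forward(f, g) * s)
    rhs <- sum(f * back_project(s, g))
    expect_lt(abs(lhs - rhs) / abs(lhs), 1e-6)
  }
  f1 <- matrix(runif(16^2), 16); f2 <- matrix(runif(16^2), 16)
  expect_equal(radon_forward(2 * f1 - 3 * f2, g),
               2 * radon_forward(f1, g) - 3 * radon_forward(f2, g),
               tolerance = 1e-12)
  expect_equal(radon_forward(matrix(0, 16, 16), g),
               matrix(0, g$n_views, g$n_bins))
  expect_equal(back_project(matrix(0, g$n_views, g$n_bins), g),
               matrix(0, 16, 16))
})

test_that("projections integrate chord lengths and are view independent", {
  g <- test_geom(128)
  disc <- smooth_disc(128, 30, 0.1)
  sino <- radon_forward(disc, g)
  ## central chord of a constant disc: 2 * r * c (in cm via pixel_size)
  expect_equal(max(sino), 2 * 30 * 0.1 * g$pixel_size, tolerance = 0.01)
  ## rotational consistency of a centrally symmetric phantom
  dev <- apply(sino, 2, function(col) max(col) - min(col))
  expect_lt(max(dev) / max(sino), 0.01)
})

test_that("integral-weighted back projection approximates the angular integral", {
  g <- test_geom(128)
  ones <- matrix(1, g$n_views, g$n_bins)
  bp <- back_project(ones, g, weight = "integral")
  expect_equal(mean(bp[40:88, 40:88]), pi, tolerance = 0.02)
})

test_that("unit conversions invert each other around the water point", {
  expect_equal(as_vec <- as.vector(hu_to_mu(matrix(0, 2, 2))), rep(0.19, 4))
  expect_equal(as.vector(hu_to_mu(matrix(-1000, 2, 2))), rep(0, 4))
  expect_equal(as.vector(hu_to_mu(matrix(1000, 2, 2))), rep(0.38, 4))
  expect_equal(as.vector(mu_to_hu(matrix(0.19, 2, 2))), rep(0, 4))
  expect_equal(as.vector(mu_to_hu(matrix(0.095, 2, 2))), rep(-500, 4))
  x <- matrix(seq(-1000, 2000, length.out = 9), 3)
  expect_equal(as.vector(mu_to_hu(hu_to_mu(x))), as.vector(x),
               tolerance = 1e-12)
  ## HU images must be converted before projection
  expect_error(radon_forward(ct_image(matrix(1, 16, 16), "hu"), test_geom(16)),
               "1/cm")
})
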