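test_that("the DCT dictionary is unitary with a constant DC atom", {
  dict <- dct_dictionary(11)
  expect_equal(ncol(dict$D), 121)
  expect_lt(max(abs(crossprod(dict$D) - diag(121))), 1e-10)
  expect_equal(dict$D[, 1], rep(1 / 11, 121))
})

test_that("patch extraction and overlap averaging cover every pixel", {
  set.seed(1)
  sig <- matrix(rnorm(16 * 16), 16)
  ep <- extract_patches(sig, 11, 1)
  expect_equal(ncol(ep$patches), 36)          # (16 - 11 + 1)^2
  ## identity processing reproduces the signal exactly
  expect_equal(reassemble_patches(ep$patches, ep$map), sig, tolerance = 1e-12)
  ## corners belong to exactly 1 patch
  counts <- matrix(ep$map$counts, 16)
  expect_equal(counts[1, 1], 1)
  ## on a signal wide enough, interior pixels sit in d^2 = 121 patches
  ep_big <- extract_patches(matrix(0, 32, 32), 11, 1)
  expect_equal(matrix(ep_big$map$counts, 32)[16, 16], 121)
  ## non-overlapping tiling at stride = d
  sig2 <- matrix(rnorm(22 * 22), 22)
  ep2 <- extract_patches(sig2, 11, 11)
  expect_true(all(ep2$map$counts == 1))
  expect_equal(reassemble_patches(ep2$patches, ep2$map), sig2)
  ## flush-to-border patches guarantee coverage at awkward strides
  ep3 <- extract_patches(matrix(rnorm(30 * 30), 30), 11, 7)
  expect_true(all(ep3$map$counts >= 1))
  expect_error(extract_patches(matrix(0, 5, 5), 11, 1), "smaller")
})

test_that("knot domains span the training dynamic range evenly", {
  co <- matrix(0, 3, 10)
  co[1, 1] <- -10; co[2, 4] <- 2.5
  q <- build_knot_domains(co, 20)
  expect_equal(q[1, ], seq(0.5, 10, by = 0.5))
  expect_equal(q[2, 20], 2.5)
  expect_equal(q[3, ], seq(0.05, 1, by = 0.05))  # all-zero band guard
  expect_error(build_knot_domains(co, 1), "K")
})

test_that("shrinkage functions are antisymmetric, anchored at zero, identity at p = q", {
  set.seed(2)
  dict <- dct_dictionary(5)
  coeffs <- matrix(rnorm(25 * 200, sd = 3), 25)
  q <- build_knot_domains(coeffs, 20)
  id <- shrinkage_params(q)
  expect_equal(apply_shrinkage(coeffs, id), coeffs, tolerance = 1e-12)
  p <- matrix(rnorm(25 * 20), 25)
  sp <- shrinkage_params(q, p)
  out <- apply_shrinkage(coeffs, sp)
  expect_equal(apply_shrinkage(-coeffs, sp), -out, tolerance = 1e-12)
  expect_equal(apply_shrinkage(matrix(0, 25, 4), sp), matrix(0, 25, 4))
  ## affine in p at fixed input (the property training relies on)
  p2 <- matrix(rnorm(25 * 20), 25)
  expect_equal(
    apply_shrinkage(coeffs, shrinkage_params(q, 2 * p + 3 * p2)),
    2 * out + 3 * apply_shrinkage(coeffs, shrinkage_params(q, p2)),
    tolerance = 1e-10)
})

test_that("the slice transform reproduces coefficients and shrinkage exactly", {
  set.seed(3)
  K <- 20
  q <- build_knot_domains(matrix(rnorm(1000, sd = 4), 1), K)
  ## includes out-of-range values (beyond the last knot) and zeros
  alpha <- c(rnorm(5000, sd = 4), 3 * max(abs(q)), -3 * max(abs(q)), 0)
  U <- slice_transform(alpha, q[1, ])
  expect_lt(max(abs(as.vector(U %*% q[1, ]) - alpha)), 1e-10)
  expect_true(all(abs(U[length(alpha), ]) == 0))  # alpha = 0 row is empty
  for (rep in 1:10) {
    p <- rnorm(K)
    direct <- apply_shrinkage(matrix(alpha, 1), shrinkage_params(q, matrix(p, 1)))
    expect_lt(max(abs(as.vector(U %*% p) - direct)), 1e-10)
  }
})

test_that("the shrinkage filter reduces noise on piecewise-constant images", {
  set.seed(4)
  dict <- dct_dictionary(8)
  truth <- matrix(0, 64, 64)
  truth[20:45, 10:30] <- 4
  truth[5:15, 40:60] <- -2
  noisy <- truth + matrix(rnorm(64^2), 64)
  ep <- extract_patches(noisy, 8, 1)
  q <- build_knot_domains(crossprod(dict$D, ep$patches), 20)
  ## identity and annihilation limits
  expect_equal(shrinkage_filter(noisy, dict, shrinkage_params(q)), noisy,
               tolerance = 1e-8)
  expect_equal(shrinkage_filter(noisy, dict, shrinkage_params(q, 0 * q)),
               matrix(0, 64, 64))
  ## soft-threshold-shaped p: keep DC, threshold the rest at 2 sigma
  p <- pmax(q - 2, 0); p[1, ] <- q[1, ]
  den <- shrinkage_filter(noisy, dict, shrinkage_params(q, p))
  expect_lt(mean((den - truth)^2), mean((noisy - truth)^2))
})
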