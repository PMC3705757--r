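## 3x3 box blur used by the MSEg blur test
sep_conv_ref <- function(f) shrinkct:::sep_conv(f, rep(1 / 3, 3))

test_that("the one-sided Huber penalty is continuous with continuous slope", {
  d <- 2
  expect_equal(huber_psi(-3, d), 0)
  expect_equal(huber_psi(d - 1e-12, d), huber_psi(d + 1e-12, d),
               tolerance = 1e-9)
  expect_equal(huber_psi(d, d), d^2 / 2)
  ## derivative continuity at the joints: the central difference converges
  ## to a common value from both sides (kinks would leave an O(1) gap)
  h <- 1e-4
  for (x0 in c(0, d)) {
    num <- (huber_psi(x0 + h, d) - huber_psi(x0 - h, d)) / (2 * h)
    expect_lt(abs(num - shrinkct:::huber_psi_grad(x0, d)), 1e-4)
  }
  expect_equal(huber_psi(5, d), d * 5 - d^2 / 2)
})

test_that("HU mask and gradient weight select the intended regions", {
  qc <- quality_config()
  ref <- matrix(54, 8, 8); ref[1, 1] <- 1000; ref[2, 2] <- -500
  H <- make_hu_mask(ref, qc)
  expect_equal(H[1, 1], 0); expect_equal(H[2, 2], 0); expect_equal(H[4, 4], 1)
  expect_true(all(make_hu_mask(ref, quality_config(hu_window = c(-1e9, 1e9))) == 1))
  ## constant reference: all-ones weight (no 0/0)
  expect_true(all(make_gradient_weight(matrix(5, 8, 8), qc) == 1))
  ## a sharp edge is excised exactly where its gradient is large
  ref2 <- matrix(0, 8, 8); ref2[, 5:8] <- 1000
  W <- make_gradient_weight(ref2, qc)
  gn <- sqrt(shrinkct:::grad_norm_sq(ref2))
  expect_equal(W, (gn <= 0.02 * max(gn)) * 1)
  expect_true(all(make_gradient_weight(ref2, quality_config(w_threshold = 1)) == 1))
})

test_that("MSEg decomposes exactly and behaves like a loss", {
  qc <- quality_config()
  ph <- test_phantom(32)
  m0 <- mseg(ph, ph, qc)
  expect_equal(m0$mseg_total, 0)
  set.seed(9)
  noisy <- as_matrix_image(ph) + matrix(rnorm(1024, 0, 10), 32)
  m <- mseg(ph, noisy, qc)
  expect_equal(m$mseg_total, m$mse_weighted + qc$mu * m$grad_penalty)
  ## mu = 0 reduces to the weighted squared error
  m_mu0 <- mseg(ph, noisy, quality_config(mu = 0))
  expect_equal(m_mu0$mseg_total, m_mu0$mse_weighted)
  ## blur induces a positive gradient penalty that shrinks as blur vanishes
  blur <- function(f, k) { for (i in seq_len(k)) f <- sep_conv_ref(f); f }
  Q1 <- mseg(ph, blur(as_matrix_image(ph), 1), qc)$grad_penalty
  Q3 <- mseg(ph, blur(as_matrix_image(ph), 3), qc)$grad_penalty
  expect_gt(Q1, 0)
  expect_gt(Q3, Q1)
})

test_that("the MSEg gradient passes finite-difference checks", {
  qc <- quality_config()
  ph <- test_phantom(32)
  set.seed(10)
  f <- as_matrix_image(ph) + matrix(rnorm(1024, 0, 25), 32)
  L <- mseg(ph, f, qc, gradient = TRUE)
  h <- 1e-4
  idx <- cbind(sample(5:28, 10, TRUE), sample(5:28, 10, TRUE))
  for (k in seq_len(nrow(idx))) {
    fp <- f; fm <- f
    fp[idx[k, 1], idx[k, 2]] <- fp[idx[k, 1], idx[k, 2]] + h
    fm[idx[k, 1], idx[k, 2]] <- fm[idx[k, 1], idx[k, 2]] - h
    num <- (mseg(ph, fp, qc)$mseg_total - mseg(ph, fm, qc)$mseg_total) / (2 * h)
    ana <- L$gradient[idx[k, 1], idx[k, 2]]
    expect_lt(abs(ana - num) / max(1, abs(num)), 1e-5)
  }
})

test_that("SNR scale search matches a 1D search and is scale invariant", {
  set.seed(11)
  f <- matrix(rnorm(400), 20)
  e <- matrix(rnorm(400), 20)
  e <- e - f * sum(e * f) / sum(f * f)      # orthogonal error
  e <- e / sqrt(sum(e^2)) * 0.01 * sqrt(sum(f^2))  # 1% energy
  fh <- f + e
  ## small orthogonal error: alpha* ~ 1 and SNR ~ -20 log10(||e||/||f||)
  expect_equal(snr(f, fh), -20 * log10(sqrt(sum(e^2)) / sqrt(sum(f^2))),
               tolerance = 1e-4)
  ## closed-form alpha* agrees with a 1D numerical search over alpha
  opt <- stats::optimize(function(a) sum((f - a * fh)^2), c(0.5, 1.5),
                         tol = 1e-12)
  expect_equal(snr(f, fh),
               -20 * log10(sqrt(opt$objective) / sqrt(sum(f^2))),
               tolerance = 1e-6)
  expect_equal(snr(f, 2 * f), snr(f, f))
  expect_equal(snr(f, f), 300)
})

test_that("SSIM matches an independent reference and responds to noise", {
  i <- matrix(rep(1:64, 64), 64); j <- t(i)
  f <- sin(i / 3) * cos(j / 5) + 0.1 * sin(i * j / 50)
  fh <- f + 0.2 * sin(7.3 * i + 11.1 * j)
  ## frozen from scikit-image structural_similarity (gaussian_weights,
  ## sigma = 1.5, use_sample_covariance = FALSE) on this exact fixture
  expect_equal(ssim(f, fh, data_range = diff(range(f))), 0.857373470314793,
               tolerance = 1e-9)
  expect_equal(ssim(f, f), 1)
  expect_equal(ssim(f, fh), ssim(fh, f, data_range = diff(range(f))))
  set.seed(12)
  vals <- vapply(c(0.05, 0.15, 0.4), function(s)
    ssim(f, f + matrix(rnorm(64^2, 0, s), 64)), numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("quality reports satisfy the MSEg identity", {
  ph <- test_phantom(32)
  set.seed(13)
  noisy <- ct_image(as_matrix_image(ph) + matrix(rnorm(1024, 0, 15), 32), "hu")
  qc <- quality_config()
  rep1 <- quality_report(ph, noisy, qc)
  expect_equal(rep1$mseg_total, rep1$mse_weighted + qc$mu * rep1$grad_penalty)
  expect_lt(rep1$ssim, 1)
})

test_that("FWHM probe recovers the closed-form width of known responses", {
  ph <- matrix(50, 96, 96)
  ## Gaussian PSF sigma = 1 px: FWHM = 2 sqrt(2 ln 2) = 2.355
  taps <- exp(-(-5:5)^2 / 2); taps <- taps / sum(taps)
  psf_recon <- function(img) shrinkct:::sep_conv(img, taps)
  res <- lir_fwhm(psf_recon, ph, n_spikes = 60, refine = 16, window = 4,
                  intensity = 1000, rng_seed = 21)
  expect_equal(res$mean_fwhm, 2 * sqrt(2 * log(2)), tolerance = 0.1)
  expect_lt(stats::sd(res$fwhm), 0.1)
  ## identity reconstructor: single-pixel response
  res_id <- lir_fwhm(identity, ph, n_spikes = 30, refine = 16, window = 3,
                     intensity = 1000, rng_seed = 22)
  expect_equal(res_id$mean_fwhm, 1, tolerance = 0.15)
})
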