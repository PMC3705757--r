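test_that("ATM local parameters follow the count-adaptive formulas", {
  p <- atm_params(beta = 1, lam = 100, delta = 0, alpha_m = 0.2)
  lp <- atm_local_params(100, p)
  expect_equal(lp$M, 100)
  expect_equal(lp$alpha, 0.2)
  ## low counts get maximal smoothing M = 2 beta lam
  p2 <- atm_params(beta = 1, lam = 100, delta = 50, alpha_m = 0.1)
  expect_equal(atm_local_params(10, p2)$M, 200)
  expect_equal(atm_local_params(50, p2)$M, 200)
  ## M strictly decreases beyond delta
  Ms <- atm_local_params(c(60, 100, 500, 5000), p2)$M
  expect_true(all(diff(Ms) < 0))
  ## alpha clipped into [0, 0.5)
  expect_lt(atm_local_params(1e9, p)$alpha, 0.5)
})

test_that("the ATM filter averages, trims, and preserves constants", {
  set.seed(14)
  y <- matrix(rpois(30 * 40, 100), 30)
  ## alpha = 0: plain neighborhood mean (variance drops ~M-fold)
  p_mean <- atm_params(beta = 0.05, lam = 100, delta = 1e9, alpha_m = 0)
  expect_equal(atm_local_params(50, p_mean)$M, 10)  # fixed M everywhere
  out <- atm_filter(y, p_mean)
  expect_lt(var(as.vector(out[5:26, 5:36])), var(as.vector(y)) / 5)
  ## constant input is untouched
  const <- matrix(77, 12, 15)
  expect_equal(atm_filter(const, atm_params(beta = 0.2, lam = 100)), const)
  ## M = 1 (tiny beta) with alpha = 0 is the identity
  p_id <- atm_params(beta = 1e-9, lam = 1, alpha_m = 0)
  expect_equal(atm_filter(y, p_id), y)
})

test_that("ATM trimming rejects low-count outliers that a plain mean keeps", {
  ## a dead bin (photon starvation) inside a homogeneous region
  y <- matrix(1000, 15, 15)
  y[8, 8] <- 0
  ## fixed 9-bin neighborhood; alpha = 0.2 at the background count level
  p_plain <- atm_params(beta = 0.0045, lam = 1000, delta = 1e9, alpha_m = 0)
  p_trim <- p_plain; p_trim$alpha_m <- 0.2
  expect_equal(atm_local_params(1000, p_plain)$M, 9)
  out_plain <- atm_filter(y, p_plain)
  out_trim <- atm_filter(y, p_trim)
  nb <- out_plain[7:9, 7:9][-5]                 # outlier's neighbors
  expect_gt(max(abs(nb - 1000)), 50)            # mean smears the dead bin
  nb_t <- out_trim[7:9, 7:9][-5]
  expect_lt(max(abs(nb_t - 1000)), 1e-9)        # trimming discards it
})

test_that("PWLS weights, objective and gradient match the model", {
  fx <- small_train_fixture()
  y <- fx$tset$items[[1]]$y
  ## W = y^2/(y + sigma_n^2); at sigma_n = 0, W = y
  o <- pwls_objective(matrix(0, 32, 32), matrix(100, fx$geom$n_views,
                                                fx$geom$n_bins),
                      pwls_config(gamma = 0), scan_model(sigma_n = 0),
                      fx$geom)
  expect_true(is.finite(o$value))
  ## truth with noiseless data and gamma = 0: zero objective and gradient
  ph <- test_phantom(32)
  ideal <- fx$model$lambda0 * exp(-radon_forward(hu_to_mu(ph), fx$geom))
  o0 <- pwls_objective(as_matrix_image(ph), ideal, pwls_config(gamma = 0),
                       fx$model, fx$geom)
  expect_lt(o0$value, 1e-4 * sum(ideal))
  expect_lt(max(abs(o0$gradient)), 1e-6 * max(abs(ideal)))
  ## finite-difference gradient check on a perturbed image
  set.seed(15)
  f <- as_matrix_image(ph) + matrix(rnorm(1024, 0, 20), 32)
  o1 <- pwls_objective(f, y, pwls_config(), fx$model, fx$geom)
  h <- 1e-4
  for (k in 1:6) {
    i <- sample(32, 1); j <- sample(32, 1)
    fp <- f; fm <- f
    fp[i, j] <- fp[i, j] + h; fm[i, j] <- fm[i, j] - h
    num <- (pwls_objective(fp, y, pwls_config(), fx$model, fx$geom)$value -
            pwls_objective(fm, y, pwls_config(), fx$model, fx$geom)$value) /
      (2 * h)
    expect_lt(abs(o1$gradient[i, j] - num) / max(1, abs(num)), 1e-4)
  }
})

test_that("PWLS descends monotonically and converges on noiseless data", {
  fx <- small_train_fixture()
  ph <- test_phantom(32)
  ideal <- fx$model$lambda0 * exp(-radon_forward(hu_to_mu(ph), fx$geom))
  rec <- pwls_reconstruct(ideal, pwls_config(gamma = 0, n_iters = 120),
                          fx$model, fx$geom)
  tr <- attr(rec, "trace")
  expect_true(all(diff(tr) <= 0))
  g_init <- pwls_objective(
    as_matrix_image(mu_to_hu(fbp_reconstruct(
      counts_to_sinogram(ideal, fx$model), fx$geom,
      fbp_filter_spec(phi0 = 1)))),
    ideal, pwls_config(gamma = 0), fx$model, fx$geom)$gradient
  g_fin <- pwls_objective(as_matrix_image(rec), ideal,
                          pwls_config(gamma = 0), fx$model, fx$geom)$gradient
  expect_lt(sqrt(sum(g_fin^2)), 1e-3 * sqrt(sum(g_init^2)))
})

test_that("PWLS is insensitive to its initialization (convexity)", {
  fx <- small_train_fixture()
  ph <- test_phantom(32)
  y <- fx$tset$items[[1]]$y
  cfg <- pwls_config(gamma = 1e-4, n_iters = 200)
  set.seed(16)
  r1 <- pwls_reconstruct(y, cfg, fx$model, fx$geom)
  r2 <- pwls_reconstruct(y, cfg, fx$model, fx$geom,
                         init = ct_image(matrix(rnorm(1024, 0, 100), 32), "hu"))
  s1 <- snr(clamp_window(ph), clamp_window(r1))
  s2 <- snr(clamp_window(ph), clamp_window(r2))
  expect_lt(abs(s1 - s2), 0.1)
})
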