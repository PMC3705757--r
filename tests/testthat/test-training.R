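test_that("identity shrinkage collapses stage I to plain FBP", {
  fx <- small_train_fixture()
  y <- fx$tset$items[[1]]$y
  rec_id <- reconstruct_stage1(y, shrinkage_params(fx$q), fx$dict, fx$geom,
                               fx$model, fx$stride)
  rec_fbp <- mu_to_hu(fbp_reconstruct(counts_to_sinogram(y, fx$model),
                                      fx$geom))
  expect_equal(as_matrix_image(rec_id), as_matrix_image(rec_fbp),
               tolerance = 1e-6)
  ## deterministic
  rec2 <- reconstruct_stage1(y, shrinkage_params(fx$q), fx$dict, fx$geom,
                             fx$model, fx$stride)
  expect_identical(as_matrix_image(rec_id), as_matrix_image(rec2))
})

test_that("the stage-I objective gradient passes finite-difference checks", {
  fx <- small_train_fixture()
  prep <- shrinkct:::stage1_prep(fx$tset, fx$dict, fx$q, fx$stride)
  qc <- quality_config()
  set.seed(17)
  p0 <- as.vector(fx$q) * (1 + 0.05 * rnorm(length(fx$q)))
  obj <- shrinkct:::sinogram_objective(p0, prep, fx$q, fx$dict, fx$geom,
                                       fx$model, qc, 1e-4)
  h <- 1e-4
  for (k in sample(length(p0), 10)) {
    pp <- p0; pm <- p0
    pp[k] <- pp[k] + h; pm[k] <- pm[k] - h
    num <- (shrinkct:::sinogram_objective(pp, prep, fx$q, fx$dict, fx$geom,
                                          fx$model, qc, 1e-4)$value -
            shrinkct:::sinogram_objective(pm, prep, fx$q, fx$dict, fx$geom,
                                          fx$model, qc, 1e-4)$value) / (2 * h)
    expect_lt(abs(obj$gradient[k] - num) / max(1, abs(num)), 1e-4)
  }
  ## regularizer vanishes at p = q; with mu = 0, gamma = 0 the objective at
  ## p = q is the H-weighted MSE of plain FBP
  qc0 <- quality_config(mu = 0)
  v_id <- shrinkct:::sinogram_objective(as.vector(fx$q), prep, fx$q, fx$dict,
                                        fx$geom, fx$model, qc0, 0)$value
  fbp <- mu_to_hu(fbp_reconstruct(
    counts_to_sinogram(fx$tset$items[[1]]$y, fx$model), fx$geom))
  expect_equal(v_id,
               mseg(fx$tset$items[[1]]$f0, fbp, qc0)$mse_weighted,
               tolerance = 1e-6)
})

test_that("the stage-II objective gradient passes finite-difference checks", {
  fx <- small_train_fixture()
  ph <- test_phantom(32)
  f1 <- reconstruct_stage1(fx$tset$items[[1]]$y, shrinkage_params(fx$q),
                           fx$dict, fx$geom, fx$model, fx$stride)
  ep <- extract_patches(as_matrix_image(f1), 11, fx$stride)
  c2 <- crossprod(fx$dict$D, ep$patches)
  q2 <- build_knot_domains(c2, 20)
  prep2 <- list(list(f0 = as_matrix_image(ph), map = ep$map,
                     w = shrinkct:::slt_weights(c2, q2)))
  qc <- quality_config()
  set.seed(18)
  p0 <- as.vector(q2) * (1 + 0.05 * rnorm(length(q2)))
  obj <- shrinkct:::image_objective(p0, prep2, q2, fx$dict, qc, 250)
  h <- 1e-4
  for (k in sample(length(p0), 8)) {
    pp <- p0; pm <- p0
    pp[k] <- pp[k] + h; pm[k] <- pm[k] - h
    num <- (shrinkct:::image_objective(pp, prep2, q2, fx$dict, qc, 250)$value -
            shrinkct:::image_objective(pm, prep2, q2, fx$dict, qc, 250)$value) /
      (2 * h)
    expect_lt(abs(obj$gradient[k] - num) / max(1, abs(num)), 1e-4)
  }
  ## at p = q the objective is the MSEg of the stage-I image itself
  v_id <- shrinkct:::image_objective(as.vector(q2), prep2, q2, fx$dict,
                                     qc, 250)$value
  expect_equal(v_id, mseg(ph, f1, qc)$mseg_total, tolerance = 1e-8)
})

test_that("training descends, is deterministic, and stays near identity without noise", {
  geom <- test_geom(32)
  phantoms <- lapply(31:33, function(i) test_phantom(32, i))
  fit <- shrinkct(phantoms, geom = geom, model = scan_model(),
                  stride = 3, max_iter = c(15, 10), seed = 4)
  expect_lte(fit$logs$stage1[length(fit$logs$stage1)], fit$logs$stage1[1])
  expect_lte(fit$logs$stage2[length(fit$logs$stage2)], fit$logs$stage2[1])
  expect_true(all(diff(fit$logs$stage1) <= 0))
  fit2 <- shrinkct(phantoms, geom = geom, model = scan_model(),
                   stride = 3, max_iter = c(15, 10), seed = 4)
  expect_identical(fit$stage1$p, fit2$stage1$p)
  expect_identical(fit$stage2$p, fit2$stage2$p)
  ## near-noiseless data: identity is near-optimal, p* stays close to q
  quiet <- scan_model(lambda0 = 1e9, sigma_n = 0)
  fitq <- shrinkct(phantoms[1], geom = geom, model = quiet,
                   stride = 3, max_iter = c(20, 5), seed = 4)
  dev <- sqrt(sum((fitq$stage1$p - fitq$stage1$q)^2) /
                sum(fitq$stage1$q^2))
  expect_lt(dev, 0.05)
})

test_that("prediction stages chain consistently", {
  geom <- test_geom(32)
  phantoms <- lapply(31:33, function(i) test_phantom(32, i))
  fit <- shrinkct(phantoms, geom = geom, model = scan_model(),
                  stride = 3, max_iter = c(10, 5), seed = 4)
  ph <- test_phantom(32, 40)
  y <- simulate_counts(radon_forward(hu_to_mu(ph), geom), fit$model,
                       seed = 123)
  r_fbp <- predict(fit, y, stage = "fbp")
  r_s1 <- predict(fit, y, stage = "stage1")
  r_full <- predict(fit, y, stage = "full")
  expect_equal(dim(r_full), c(32L, 32L))
  ## stage-2 filtering of the stage-1 image reproduces "full"
  manual <- shrinkage_filter(as_matrix_image(r_s1), fit$dict, fit$stage2,
                             fit$stride_image)
  expect_equal(as_matrix_image(r_full), manual, tolerance = 1e-12)
  ## methods exist and run
  expect_output(print(fit), "learned-shrinkage")
  expect_output(print(summary(fit)), "deviation")
  co <- coef(fit)
  expect_equal(dim(co$stage1$p), c(121L, 20L))
  sims <- simulate(fit, nsim = 2, seed = 5, phantom = ph)
  expect_length(sims, 2)
  expect_identical(sims, simulate(fit, nsim = 2, seed = 5, phantom = ph))
})
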