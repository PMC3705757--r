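#' Assemble a training set of reference images and simulated measurements
#'
#' For each reference HU phantom: convert to attenuation, project to a
#' noiseless sinogram, and draw one fixed noisy count realization (seeded per
#' item, so the set is reproducible).
#'
#' @param phantoms list of HU images ([ct_image()] or matrices).
#' @param geom a [ct_geometry()] shared by all items.
#' @param model a [scan_model()] shared by all items.
#' @param seed base integer seed; item i uses `seed + i`.
#' @return object of class `ct_training_set`: list of items
#'   (`f0` HU image, `sino` noiseless line integrals, `y` counts), plus the
#'   geometry and scan model.
#' @export
ct_training_set <- function(phantoms, geom, model, seed = 1L) {
  if (length(phantoms) < 1) stop("training set must contain at least one image")
  items <- lapply(seq_along(phantoms), function(i) {
    f0 <- phantoms[[i]]
    if (image_units(f0) != "hu") stop("training phantoms must be HU images")
    sino <- radon_forward(hu_to_mu(f0), geom)
    list(f0 = f0, sino = sino,
         y = simulate_counts(sino, model, seed = seed + i))
  })
  structure(list(items = items, geom = geom, model = model, seed = seed),
            class = "ct_training_set")
}

#' @export
print.ct_training_set <- function(x, ...) {
  cat(sprintf("CT training set: %d items, %d x %d images, lambda0 = %.3g\n",
              length(x$items), x$geom$n, x$geom$n, x$model$lambda0))
  invisible(x)
}

## Precompute everything about one item that is fixed during stage-I
## optimization: the stabilized data, its patch DCT coefficients and their
## slice-transform weights on the frozen knot grid.
stage1_prep <- function(tset, dict, q, stride) {
  lapply(tset$items, function(it) {
    z <- omega_forward(it$y, tset$model)
    ep <- extract_patches(z, dict$d, stride)
    coeffs <- crossprod(dict$D, ep$patches)
    list(f0 = as_matrix_image(it$f0), map = ep$map,
         w = slt_weights(coeffs, q))
  })
}

#' Stage-I (sinogram-domain) training objective and gradient
#'
#' `Gamma_p = sum_items MSEg(f0, f_p(z)) + gamma * ||p - q||^2`, where
#' `f_p(z)` runs the full chain: shrink the stabilized data, invert the
#' Anscombe adjustment, log-transform, FBP, convert to HU. The gradient
#' chains the MSEg gradient through the linear FBP adjoint, the elementwise
#' derivative of the inverse adjustment and log, and the slice-transform
#' linear path.
#'
#' @param p_vec flat parameter vector (`n_bands * K`).
#' @param prep per-item precomputation from the internal stage-I setup
#'   (stabilized data coefficients and slice-transform weights on frozen
#'   knot domains).
#' @param q knot-domain matrix the regularizer is anchored to.
#' @param dict a [dct_dictionary()].
#' @param geom,model geometry and scan model.
#' @param config a [quality_config()].
#' @param gamma regularizer weight.
#' @return list with `value` and `gradient` (flat vector).
#' @keywords internal
sinogram_objective <- function(p_vec, prep, q, dict, geom, model, config,
                               gamma) {
  P <- matrix(p_vec, nrow = nrow(q))
  value <- gamma * sum((P - q)^2)
  grad <- 2 * gamma * (P - q)
  hu_scale <- 1000 / MU_WATER
  for (it in prep) {
    S <- matrix(slt_eval(it$w, P), nrow = nrow(q))
    u <- reassemble_patches(dict$D %*% S, it$map)
    raw <- (u / 2)^2 - 3 / 8 - model$sigma_n^2
    active <- raw > 1
    y2 <- pmax(raw, 1)
    g <- log(model$lambda0) - log(y2)
    f_mu <- fbp_reconstruct(g, geom)
    f_hu <- as_matrix_image(f_mu) * hu_scale - 1000
    L <- mseg(it$f0, f_hu, config, gradient = TRUE)
    value <- value + L$mseg_total
    if (!is.finite(value)) stop("non-finite stage-I objective")
    Gg <- fbp_adjoint(L$gradient * hu_scale, geom)
    Gu <- (-Gg / y2) * active * (u / 2)
    ext <- matrix((Gu / it$map$counts)[it$map$idx], nrow = dict$d^2)
    grad <- grad + slt_grad_p(it$w, crossprod(dict$D, ext))
  }
  list(value = value, gradient = as.vector(grad))
}

#' Stage-II (image-domain) training objective and gradient
#'
#' `Gamma^I = sum_items MSEg(f0, G_pI(f1)) + gamma_I * ||pI - qI||^2`, where
#' `f1` are the stage-I reconstructions. No tomography in the chain: the
#' gradient goes straight through the slice-transform linear path.
#'
#' @param p_vec flat parameter vector.
#' @param prep per-item precomputation (stage-I image patch coefficients and
#'   weights).
#' @param q knot-domain matrix.
#' @param dict a [dct_dictionary()].
#' @param config a [quality_config()].
#' @param gamma_I regularizer weight.
#' @return list with `value` and `gradient`.
#' @keywords internal
image_objective <- function(p_vec, prep, q, dict, config, gamma_I) {
  P <- matrix(p_vec, nrow = nrow(q))
  value <- gamma_I * sum((P - q)^2)
  grad <- 2 * gamma_I * (P - q)
  for (it in prep) {
    S <- matrix(slt_eval(it$w, P), nrow = nrow(q))
    fI <- reassemble_patches(dict$D %*% S, it$map)
    L <- mseg(it$f0, fI, config, gradient = TRUE)
    value <- value + L$mseg_total
    if (!is.finite(value)) stop("non-finite stage-II objective")
    ext <- matrix((L$gradient / it$map$counts)[it$map$idx], nrow = dict$d^2)
    grad <- grad + slt_grad_p(it$w, crossprod(dict$D, ext))
  }
  list(value = value, gradient = as.vector(grad))
}

## L-BFGS driver with shared value/gradient computation and an evaluation
## trace. Returns par, trace of accepted (cumulative-best) objective values.
lbfgs_drive <- function(par0, obj_fn, maxit, verbose = FALSE) {
  env <- new.env()
  env$last_par <- NULL
  env$trace <- numeric(0)
  evaluate <- function(p) {
    if (!identical(p, env$last_par)) {
      env$last <- obj_fn(p)
      env$last_par <- p
      env$trace <- c(env$trace, env$last$value)
      if (verbose && length(env$trace) %% 10 == 1)
        message(sprintf("  eval %d: objective %.6g",
                        length(env$trace), env$last$value))
    }
    env$last
  }
  res <- stats::optim(par0,
                      fn = function(p) evaluate(p)$value,
                      gr = function(p) evaluate(p)$gradient,
                      method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = 1e4))
  if (!is.finite(res$value)) stop("optimizer diverged (non-finite objective)")
  list(par = res$par, value = res$value, trace = cummin(env$trace),
       evals = length(env$trace), convergence = res$convergence)
}

#' Stage-I reconstruction: shrink the stabilized sinogram, then FBP
#'
#' `f_p(z) = -T(log((1/lambda0) * omega^-1(G_p(omega(y)))))` with `T` the
#' unwindowed FBP. With identity shrinkage (`p = q`) this collapses to plain
#' FBP of the log-transformed counts.
#'
#' @param y photon-count matrix.
#' @param params a [shrinkage_params()] for the sinogram domain.
#' @param dict a [dct_dictionary()].
#' @param geom,model geometry and scan model.
#' @param stride patch stride.
#' @return HU-flagged [ct_image()].
#' @export
reconstruct_stage1 <- function(y, params, dict, geom, model, stride = 1) {
  z <- omega_forward(y, model)
  u <- shrinkage_filter(z, dict, params, stride)
  g <- counts_to_sinogram(omega_inverse(u, model), model)
  mu_to_hu(fbp_reconstruct(g, geom))
}

#' Two-stage learned-shrinkage CT reconstruction model
#'
#' Fits the full pipeline on a set of reference phantoms: simulates low-dose
#' measurements, freezes per-band knot domains, then learns the sinogram-
#' domain shrinkage (stage I, through the reconstruction operator) and the
#' image-domain shrinkage (stage II, on the stage-I outputs), both by L-BFGS
#' on the MSEg objective with an identity-anchored regularizer.
#'
#' @param phantoms list of HU reference images, or a [ct_training_set()]
#'   (in which case `geom`, `model` and `seed` are taken from it).
#' @param geom a [ct_geometry()]; default matches the first phantom.
#' @param model a [scan_model()]; default `lambda0 = 1.5e5`, `sigma_n = 5`.
#' @param config a [quality_config()] (MSEg weights and masks).
#' @param gamma stage-I regularizer weight (default 1e-4).
#' @param gamma_I stage-II regularizer weight (default 250).
#' @param d patch side (default 11).
#' @param K knots per shrinkage function (default 20).
#' @param stride patch stride in the sinogram domain (1 = maximal overlap;
#'   larger strides trade a little accuracy for speed).
#' @param stride_image patch stride in the image domain.
#' @param max_iter two integers: L-BFGS iteration caps for stages I and II.
#' @param seed base seed for the training-set noise realizations.
#' @param verbose print objective progress.
#' @return object of class `shrinkct` with components `stage1`, `stage2`
#'   ([shrinkage_params()]), `dict`, `geom`, `model`, `config`, `logs`
#'   (objective traces) and `stage1_train` (stage-I reconstructions of the
#'   training items).
#' @seealso [predict.shrinkct()], [plot.shrinkct()], [reconstruct_stage1()]
#' @export
shrinkct <- function(phantoms, geom = NULL, model = scan_model(),
                     config = quality_config(), gamma = 1e-4, gamma_I = 250,
                     d = 11, K = 20, stride = 1, stride_image = stride,
                     max_iter = c(100, 40), seed = 1L, verbose = FALSE) {
  cl <- match.call()
  if (inherits(phantoms, "ct_training_set")) {
    tset <- phantoms
    geom <- tset$geom; model <- tset$model
  } else {
    if (is.null(geom)) geom <- ct_geometry(nrow(phantoms[[1]]))
    tset <- ct_training_set(phantoms, geom, model, seed = seed)
  }
  dict <- dct_dictionary(d)

  ## ---- stage I: sinogram domain ----
  all_coeffs <- lapply(tset$items, function(it) {
    crossprod(dict$D,
              extract_patches(omega_forward(it$y, model), d, stride)$patches)
  })
  q1 <- build_knot_domains(do.call(cbind, all_coeffs), K)
  rm(all_coeffs)
  prep1 <- stage1_prep(tset, dict, q1, stride)
  if (verbose) message("stage I: optimizing sinogram-domain shrinkage")
  fit1 <- lbfgs_drive(as.vector(q1), function(p) {
    sinogram_objective(p, prep1, q1, dict, geom, model, config, gamma)
  }, maxit = max_iter[1], verbose = verbose)
  stage1 <- shrinkage_params(q1, matrix(fit1$par, nrow = nrow(q1)))
  rm(prep1)

  ## ---- stage II: image domain, trained on stage-I outputs ----
  recon1 <- lapply(tset$items, function(it) {
    reconstruct_stage1(it$y, stage1, dict, geom, model, stride)
  })
  coeffs2 <- lapply(recon1, function(f1) {
    crossprod(dict$D,
              extract_patches(as_matrix_image(f1), d, stride_image)$patches)
  })
  q2 <- build_knot_domains(do.call(cbind, coeffs2), K)
  rm(coeffs2)
  prep2 <- lapply(seq_along(recon1), function(i) {
    ep <- extract_patches(as_matrix_image(recon1[[i]]), d, stride_image)
    coeffs <- crossprod(dict$D, ep$patches)
    list(f0 = as_matrix_image(tset$items[[i]]$f0), map = ep$map,
         w = slt_weights(coeffs, q2))
  })
  if (verbose) message("stage II: optimizing image-domain shrinkage")
  fit2 <- lbfgs_drive(as.vector(q2), function(p) {
    image_objective(p, prep2, q2, dict, config, gamma_I)
  }, maxit = max_iter[2], verbose = verbose)
  stage2 <- shrinkage_params(q2, matrix(fit2$par, nrow = nrow(q2)))

  structure(list(
    stage1 = stage1, stage2 = stage2, dict = dict,
    geom = geom, model = model, config = config,
    gamma = gamma, gamma_I = gamma_I,
    stride = stride, stride_image = stride_image, seed = seed,
    n_train = length(tset$items),
    logs = list(stage1 = fit1$trace, stage2 = fit2$trace),
    stage1_train = recon1,
    call = cl), class = "shrinkct")
}

#' Reconstruct photon counts with a fitted model
#'
#' @param object a fitted [shrinkct()] model.
#' @param counts `n_views x n_bins` photon-count matrix measured under the
#'   model's geometry.
#' @param stage `"full"` (both stages), `"stage1"` (sinogram shrinkage +
#'   FBP only) or `"fbp"` (plain unwindowed FBP, no shrinkage).
#' @param model optional [scan_model()] describing the scan the counts came
#'   from, when it differs from the training dose (the learned shrinkage is
#'   robust across a range of doses).
#' @param ... unused.
#' @return HU-flagged [ct_image()].
#' @export
predict.shrinkct <- function(object, counts, stage = c("full", "stage1", "fbp"),
                             model = object$model, ...) {
  stage <- match.arg(stage)
  if (stage == "fbp") {
    g <- counts_to_sinogram(counts, model)
    return(mu_to_hu(fbp_reconstruct(g, object$geom)))
  }
  f1 <- reconstruct_stage1(counts, object$stage1, object$dict, object$geom,
                           model, object$stride)
  if (stage == "stage1") return(f1)
  out <- shrinkage_filter(as_matrix_image(f1), object$dict, object$stage2,
                          object$stride_image)
  ct_image(out, units = "hu")
}

#' @export
print.shrinkct <- function(x, ...) {
  cat("Two-stage learned-shrinkage CT reconstruction model\n")
  cat(sprintf("  geometry: %d x %d image, %d views x %d bins\n",
              x$geom$n, x$geom$n, x$geom$n_views, x$geom$n_bins))
  cat(sprintf("  scan: lambda0 = %.3g, sigma_n = %.3g\n",
              x$model$lambda0, x$model$sigma_n))
  cat(sprintf("  shrinkage: d = %d (%d bands), K = %d knots, strides %d/%d\n",
              x$dict$d, x$dict$d^2, x$stage1$K, x$stride, x$stride_image))
  cat(sprintf("  trained on %d images; objective %.5g -> %.5g (I), %.5g -> %.5g (II)\n",
              x$n_train,
              x$logs$stage1[1], x$logs$stage1[length(x$logs$stage1)],
              x$logs$stage2[1], x$logs$stage2[length(x$logs$stage2)]))
  invisible(x)
}

#' @export
summary.shrinkct <- function(object, ...) {
  dev <- function(s) sqrt(sum((s$p - s$q)^2) / sum(s$q^2))
  structure(list(
    model = object,
    deviation = c(stage1 = dev(object$stage1), stage2 = dev(object$stage2)),
    evals = c(stage1 = length(object$logs$stage1),
              stage2 = length(object$logs$stage2)),
    final = c(stage1 = object$logs$stage1[length(object$logs$stage1)],
              stage2 = object$logs$stage2[length(object$logs$stage2)])
  ), class = "summary.shrinkct")
}

#' @export
print.summary.shrinkct <- function(x, ...) {
  print(x$model)
  cat(sprintf("  relative deviation from identity: %.3g (I), %.3g (II)\n",
              x$deviation[1], x$deviation[2]))
  cat(sprintf("  objective evaluations: %d (I), %d (II)\n",
              x$evals[1], x$evals[2]))
  invisible(x)
}

#' @export
coef.shrinkct <- function(object, ...) {
  list(stage1 = list(q = object$stage1$q, p = object$stage1$p),
       stage2 = list(q = object$stage2$q, p = object$stage2$p))
}

#' Plot learned shrinkage functions
#'
#' Draws the positive half of selected per-band shrinkage functions against
#' the identity (dashed).
#'
#' @param x a fitted [shrinkct()] model.
#' @param stage 1 or 2.
#' @param bands band indices to plot (default: first 16).
#' @param ... passed to [graphics::plot()].
#' @export
plot.shrinkct <- function(x, stage = 1, bands = seq_len(16), ...) {
  s <- if (stage == 1) x$stage1 else x$stage2
  bands <- bands[bands <= s$n_bands]
  nb <- length(bands)
  nc <- ceiling(sqrt(nb))
  op <- graphics::par(mfrow = c(ceiling(nb / nc), nc),
                      mar = c(2, 2, 1.5, 0.5))
  on.exit(graphics::par(op))
  for (b in bands) {
    qq <- c(0, s$q[b, ]); pp <- c(0, s$p[b, ])
    graphics::plot(qq, pp, type = "l", col = "firebrick",
                   main = sprintf("band %d", b), cex.main = 0.8, ...)
    graphics::abline(0, 1, lty = 2, col = "grey50")
  }
  invisible(x)
}

#' Simulate measurements under a fitted model's scan conditions
#'
#' @param object a fitted [shrinkct()] model.
#' @param nsim number of count realizations.
#' @param seed integer seed.
#' @param phantom HU image to scan (required).
#' @param ... unused.
#' @return list of count matrices (length `nsim`).
#' @export
simulate.shrinkct <- function(object, nsim = 1, seed = NULL, phantom, ...) {
  sino <- radon_forward(hu_to_mu(phantom), object$geom)
  lapply(seq_len(nsim), function(i) {
    simulate_counts(sino, object$model,
                    seed = if (is.null(seed)) NULL else seed + i)
  })
}
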