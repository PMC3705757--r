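#' Adaptive trimmed-mean (ATM) filter parameters
#'
#' Inner parameters of the count-adaptive trimmed mean: neighborhood size
#' `M = 2 beta lam^2 / (lam + max(0, x - delta))` (large for unreliable low
#' counts, shrinking as the count grows) and trim fraction
#' `alpha = alpha_m * x / lam`, clipped to `[0, 0.5)`. The inner parameters
#' carry no prescribed scale; tune them on a training set with [atm_tune()].
#'
#' @param beta,lam,delta,alpha_m positive reals.
#' @return object of class `atm_params`.
#' @export
atm_params <- function(beta = 0.005, lam = 2000, delta = 0, alpha_m = 0.02) {
  if (beta <= 0 || lam <= 0 || alpha_m < 0)
    stop("beta, lam must be positive and alpha_m nonnegative")
  structure(list(beta = beta, lam = lam, delta = delta, alpha_m = alpha_m),
            class = "atm_params")
}

#' Local ATM neighborhood size and trim fraction
#'
#' @param x photon count value(s).
#' @param params an [atm_params()].
#' @return list with integer `M` (>= 1, rounded up) and `alpha` in
#'   `[0, 0.5)`.
#' @export
atm_local_params <- function(x, params) {
  M <- 2 * params$beta * params$lam^2 /
    (params$lam + pmax(0, x - params$delta))
  alpha <- pmin(pmax(params$alpha_m * x / params$lam, 0), 0.5 - 1e-9)
  list(M = pmax(1, ceiling(M)), alpha = alpha)
}

## neighborhood offsets sorted by Euclidean distance, ties in row-major
## order, enough to cover m_max bins
atm_offsets <- function(m_max) {
  r <- ceiling(sqrt(m_max / pi)) + 2
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g$d <- g$dr^2 + g$dc^2
  g <- g[order(g$d, g$dr, g$dc), ]
  g[seq_len(min(nrow(g), m_max)), c("dr", "dc")]
}

#' Adaptive trimmed-mean sinogram filter
#'
#' For every bin: gather the `M` nearest bins (discrete disc, including the
#' bin itself), discard the `floor(M alpha)` highest and lowest values, and
#' average the rest. `M` and `alpha` adapt to the local count via
#' [atm_local_params()]. Neighborhoods are truncated at the data boundary.
#'
#' @param y photon-count matrix.
#' @param params an [atm_params()].
#' @return filtered count matrix, same shape.
#' @export
atm_filter <- function(y, params) {
  lp <- atm_local_params(y, params)
  Mm <- matrix(lp$M, nrow(y)); Am <- matrix(lp$alpha, nrow(y))
  offs <- atm_offsets(max(Mm))
  nr <- nrow(y); nc <- ncol(y)
  out <- y
  for (j in seq_len(nc)) {
    cc <- j + offs$dc
    for (i in seq_len(nr)) {
      M <- Mm[i, j]
      if (M == 1) next
      rr <- i + offs$dr[seq_len(M)]
      c2 <- cc[seq_len(M)]
      ok <- rr >= 1 & rr <= nr & c2 >= 1 & c2 <= nc
      vals <- y[cbind(rr[ok], c2[ok])]
      t <- min(floor(length(vals) * Am[i, j]), (length(vals) - 1) %/% 2)
      if (t > 0) {
        vals <- sort.int(vals)
        vals <- vals[(t + 1):(length(vals) - t)]
      }
      out[i, j] <- mean(vals)
    }
  }
  out
}

#' Tune ATM inner parameters on training data
#'
#' Coordinate-descent grid search mirroring the protocol of tuning on the
#' training set: each round sweeps a multiplicative grid for one pair of the
#' four parameters, minimizing the mean squared error between the filtered
#' counts and the ideal (noiseless) counts.
#'
#' @param y_list list of measured count matrices.
#' @param ideal_list list of matching ideal count matrices
#'   (`lambda0 * exp(-g)`).
#' @param init an [atm_params()] starting point.
#' @param rounds coordinate-descent rounds.
#' @param grid multiplicative factors swept for each parameter.
#' @return tuned [atm_params()].
#' @export
atm_tune <- function(y_list, ideal_list, init = atm_params(), rounds = 2,
                     grid = c(0.25, 0.5, 1, 2, 4)) {
  par <- unlist(init[c("beta", "lam", "delta", "alpha_m")])
  par["delta"] <- max(par["delta"], 1)  # multiplicative grid needs > 0
  cost <- function(p) {
    pp <- atm_params(p[1], p[2], p[3], p[4])
    mean(vapply(seq_along(y_list), function(i) {
      mean((atm_filter(y_list[[i]], pp) - ideal_list[[i]])^2)
    }, numeric(1)))
  }
  pairs <- list(c(1, 2), c(3, 4), c(1, 4), c(2, 3))
  best <- cost(par)
  for (r in seq_len(rounds)) for (pr in pairs) {
    for (g1 in grid) for (g2 in grid) {
      cand <- par
      cand[pr[1]] <- par[pr[1]] * g1
      cand[pr[2]] <- par[pr[2]] * g2
      cc <- try(cost(cand), silent = TRUE)
      if (!inherits(cc, "try-error") && cc < best) {
        best <- cc; par <- cand
      }
    }
  }
  atm_params(par[1], par[2], par[3], par[4])
}

#' PWLS configuration
#'
#' @param gamma penalty weight (default 1e-3, tuned on training phantoms).
#' @param delta_huber Huber transition for the edge-preserving penalty, in
#'   HU (default 10).
#' @param n_iters L-BFGS iteration budget (default 90).
#' @return object of class `pwls_config`.
#' @export
pwls_config <- function(gamma = 1e-3, delta_huber = 10, n_iters = 90) {
  if (gamma < 0 || n_iters < 1) stop("require gamma >= 0 and n_iters >= 1")
  structure(list(gamma = gamma, delta_huber = delta_huber,
                 n_iters = as.integer(n_iters)), class = "pwls_config")
}

## symmetric Huber and derivative
huber_sym <- function(x, delta) {
  a <- abs(x)
  ifelse(a < delta, x^2 / 2, delta * a - delta^2 / 2)
}
huber_sym_grad <- function(x, delta) {
  pmin(pmax(x, -delta), delta)
}

#' PWLS objective and gradient
#'
#' Penalized weighted least squares for the CT image (HU parametrization):
#' `1/2 sum_l W_l ([R mu(f)]_l - g_l)^2 + gamma * sum_p sum_{k in N4(p)}
#' psi(f_p - f_k)` with statistical weights `W_l = y_l^2 / (y_l + sigma_n^2)`
#' (counts floored at one photon), `g = -log(y/lambda0)`, and `psi` the
#' symmetric Huber penalty on 4-neighbor differences.
#'
#' @param f HU image (matrix).
#' @param y photon-count matrix.
#' @param config a [pwls_config()].
#' @param model a [scan_model()].
#' @param geom a [ct_geometry()].
#' @return list with `value` and `gradient` (matrix shaped like `f`).
#' @export
pwls_objective <- function(f, y, config, model, geom) {
  f <- as_matrix_image(f)
  yf <- pmax(y, 1)
  W <- yf^2 / (yf + model$sigma_n^2)
  g <- counts_to_sinogram(y, model)
  c1 <- MU_WATER / 1000
  mu <- c1 * (f + 1000)
  r <- radon_forward(mu, geom) - g
  value <- 0.5 * sum(W * r^2)
  grad <- c1 * back_project(W * r, geom)
  if (config$gamma > 0) {
    nr <- nrow(f); nc <- ncol(f)
    dx <- f[, -1, drop = FALSE] - f[, -nc, drop = FALSE]
    dy <- f[-1, , drop = FALSE] - f[-nr, , drop = FALSE]
    value <- value + 2 * config$gamma *
      (sum(huber_sym(dx, config$delta_huber)) +
       sum(huber_sym(dy, config$delta_huber)))
    gx <- huber_sym_grad(dx, config$delta_huber)
    gy <- huber_sym_grad(dy, config$delta_huber)
    gpen <- matrix(0, nr, nc)
    gpen[, -1] <- gpen[, -1] + gx
    gpen[, -nc] <- gpen[, -nc] - gx
    gpen[-1, ] <- gpen[-1, ] + gy
    gpen[-nr, ] <- gpen[-nr, ] - gy
    grad <- grad + 2 * config$gamma * gpen
  }
  list(value = value, gradient = grad)
}

#' PWLS reconstruction
#'
#' Minimizes the PWLS objective by L-BFGS-B with the physical box constraint
#' `f >= -1000` HU (nonnegative attenuation), initialized from an FBP
#' reconstruction.
#'
#' @param y photon-count matrix.
#' @param config a [pwls_config()].
#' @param model a [scan_model()].
#' @param geom a [ct_geometry()].
#' @param init optional initial HU image; default is Butterworth-windowed
#'   FBP (`phi0 = 1`).
#' @return HU-flagged [ct_image()] with attribute `"trace"` holding the
#'   accepted (cumulative-best) objective values.
#' @export
pwls_reconstruct <- function(y, config = pwls_config(), model, geom,
                             init = NULL) {
  if (is.null(init)) {
    g <- counts_to_sinogram(y, model)
    init <- mu_to_hu(fbp_reconstruct(g, geom, fbp_filter_spec(phi0 = 1)))
  }
  fit <- lbfgs_drive_box(as.vector(as_matrix_image(init)), function(p) {
    o <- pwls_objective(matrix(p, geom$n), y, config, model, geom)
    list(value = o$value, gradient = as.vector(o$gradient))
  }, maxit = config$n_iters, lower = -1000)
  out <- ct_image(matrix(fit$par, geom$n), units = "hu")
  attr(out, "trace") <- fit$trace
  out
}

## boxed variant of the L-BFGS driver
lbfgs_drive_box <- function(par0, obj_fn, maxit, lower = -Inf) {
  env <- new.env()
  env$last_par <- NULL
  env$trace <- numeric(0)
  evaluate <- function(p) {
    if (!identical(p, env$last_par)) {
      env$last <- obj_fn(p)
      env$last_par <- p
      env$trace <- c(env$trace, env$last$value)
    }
    env$last
  }
  res <- stats::optim(par0,
                      fn = function(p) evaluate(p)$value,
                      gr = function(p) evaluate(p)$gradient,
                      method = "L-BFGS-B", lower = lower,
                      control = list(maxit = maxit, factr = 1e4))
  list(par = res$par, value = res$value, trace = cummin(env$trace))
}
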