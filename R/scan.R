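#' X-ray scan statistical model
#'
#' Compound Poisson-Gaussian measurement model: each detector bin records
#' `Poiss(lambda0 * exp(-g)) + Gauss(dark, sigma_n)` photons, where `g` is the
#' line integral of attenuation along the ray, `lambda0` the source photon
#' count (the dose control), `sigma_n` the electronic-noise standard deviation
#' and `dark` the electronic-noise mean (zero for modern detectors, and
#' assumed zero throughout the variance-stabilization chain).
#'
#' @param lambda0 source photon count per ray (> 0). Default 1.5e5, the
#'   training dose used throughout.
#' @param sigma_n electronic noise standard deviation in counts (>= 0).
#' @param dark electronic noise mean in counts.
#' @param rng_seed optional integer seed stored with the model and used by
#'   [simulate_counts()] when no explicit seed is given.
#' @return an object of class `scan_model`.
#' @export
scan_model <- function(lambda0 = 1.5e5, sigma_n = 5, dark = 0,
                       rng_seed = NULL) {
  if (lambda0 <= 0) stop("lambda0 must be positive")
  if (sigma_n < 0) stop("sigma_n must be nonnegative")
  structure(list(lambda0 = lambda0, sigma_n = sigma_n, dark = dark,
                 rng_seed = rng_seed), class = "scan_model")
}

#' @export
print.scan_model <- function(x, ...) {
  cat(sprintf("CT scan model: lambda0 = %.3g counts, sigma_n = %.3g, dark = %.3g\n",
              x$lambda0, x$sigma_n, x$dark))
  invisible(x)
}

#' Simulate photon counts from a sinogram
#'
#' Draws per-bin counts `Poiss(lambda0 * exp(-g)) + Gauss(dark, sigma_n)`.
#' Counts are kept real valued after the Gaussian addition. For Poisson means
#' above 1e8 (where integer-valued generation would overflow) the draw
#' switches to the asymptotically exact normal approximation
#' `lambda + sqrt(lambda) * Z`.
#'
#' @param sino `n_views x n_bins` matrix of line integrals.
#' @param model a [scan_model()].
#' @param seed optional integer seed (falls back to `model$rng_seed`; if both
#'   are `NULL` the current RNG stream is used).
#' @return matrix of simulated counts, same shape as `sino`.
#' @export
simulate_counts <- function(sino, model, seed = NULL) {
  stopifnot(inherits(model, "scan_model"))
  if (is.null(seed)) seed <- model$rng_seed
  lam <- model$lambda0 * exp(-as.vector(sino))
  with_seed(seed, {
    y <- numeric(length(lam))
    big <- lam > 1e8
    if (any(!big)) y[!big] <- stats::rpois(sum(!big), lam[!big])
    if (any(big)) y[big] <- lam[big] + sqrt(lam[big]) * stats::rnorm(sum(big))
    if (model$sigma_n > 0 || model$dark != 0)
      y <- y + stats::rnorm(length(y), model$dark, model$sigma_n)
    matrix(y, nrow = nrow(sino))
  })
}
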