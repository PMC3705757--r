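## Data adjustment chain: photon counts -> (remove Gaussian component)
## -> Anscombe transform (unit variance) -> shrinkage happens here
## -> inverse -> -log -> line integrals.

#' Remove the Gaussian component from measured counts
#'
#' Computes the adjusted counts `max(y - dark + sigma_n^2, 0)`, whose first
#' two moments match a pure Poisson variable with mean
#' `lambda + sigma_n^2`. With `dark = 0` the positivity clamp is inactive for
#' any count above `-sigma_n^2`.
#'
#' @param y matrix of measured counts.
#' @param model a [scan_model()].
#' @return matrix of adjusted counts.
#' @export
adjust_counts <- function(y, model) {
  pmax(y - model$dark + model$sigma_n^2, 0)
}

#' Variance-stabilizing data adjustment (Anscombe chain)
#'
#' The elementwise map `z = 2 * sqrt(y + sigma_n^2 + 3/8)`: Gaussian-component
#' removal (with zero-mean electronic noise) composed with the Anscombe
#' transform, bringing the compound Poisson-Gaussian counts to approximately
#' unit variance so a single shrinkage function per band can treat all
#' sinogram patches alike.
#'
#' @param y matrix of measured counts.
#' @param model a [scan_model()].
#' @return matrix in Anscombe units.
#' @export
omega_forward <- function(y, model) {
  2 * sqrt(adjust_counts(y, model) + 3 / 8)
}

#' Inverse of the variance-stabilizing adjustment
#'
#' `y = (z/2)^2 - 3/8 - sigma_n^2`, clamped below at `floor_counts` so that
#' filtered values that dip under the transform's range never produce
#' nonpositive counts for the subsequent log.
#'
#' @param z matrix in Anscombe units.
#' @param model a [scan_model()].
#' @param floor_counts lower clamp in photons (default 1).
#' @return matrix of counts.
#' @export
omega_inverse <- function(z, model, floor_counts = 1) {
  pmax((z / 2)^2 - 3 / 8 - model$sigma_n^2, floor_counts)
}

#' Log-transform counts to line integrals
#'
#' `g = -log(max(y, floor_counts) / lambda0)`; the floor guards against
#' nonpositive counts after filtering or at extreme noise.
#'
#' @param y matrix of counts.
#' @param model a [scan_model()].
#' @param floor_counts lower clamp in photons (default 1).
#' @return sinogram matrix of line integrals.
#' @export
counts_to_sinogram <- function(y, model, floor_counts = 1) {
  -log(pmax(y, floor_counts) / model$lambda0)
}
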