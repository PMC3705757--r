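#' Discrete Ram-Lak (ramp) filter kernel
#'
#' The spatial-domain taps `kappa(p) = sinc(pi p) - (1/2) sinc(pi p / 2)^2`
#' for integer offsets `p = -(m-1)/2 ... (m-1)/2`, with
#' `sinc(x) = sin(x)/x`, `sinc(0) = 1`. This is the classical band-limited
#' ramp `|omega|` sampled at unit spacing: `kappa(0) = 1/2`, odd offsets
#' `-2/(pi^2 p^2)`, even nonzero offsets exactly 0. Global amplitude is
#' calibrated downstream by [fbp_reconstruct()].
#'
#' @param m number of taps (odd, >= 3).
#' @return numeric vector of length `m`.
#' @export
ram_lak_kernel <- function(m) {
  if (m %% 2 == 0) stop("kernel tap count m must be odd")
  if (m < 3) stop("m must be at least 3")
  p <- seq.int(-(m - 1) / 2, (m - 1) / 2)
  msinc <- function(x) ifelse(x == 0, 1, sin(x) / x)
  msinc(pi * p) - 0.5 * msinc(pi * p / 2)^2
}

#' Butterworth low-pass window
#'
#' `|H(omega)| = (1 + (omega/phi0)^(2 p))^(-1/2)` on a normalized frequency
#' grid (Nyquist = 1). `phi0` is the -3 dB cutoff, `p` the roll-off order.
#'
#' @param freqs numeric vector of normalized frequencies.
#' @param phi0 cutoff frequency (> 0).
#' @param order filter order `p` (>= 1).
#' @return numeric vector of window weights in (0, 1\].
#' @export
butterworth_window <- function(freqs, phi0, order = 4) {
  if (phi0 <= 0) stop("phi0 must be positive (use phi0 = 0 upstream to disable)")
  if (order < 1) stop("butterworth order must be >= 1")
  (1 + (abs(freqs) / phi0)^(2 * order))^(-1 / 2)
}

#' FBP filter specification
#'
#' @param m kernel taps (odd); `NULL` defaults to full detector support
#'   (`n_bins` rounded up to odd) at reconstruction time.
#' @param phi0 Butterworth cutoff in normalized frequency (Nyquist = 1);
#'   `0` disables the low-pass window (pure ramp, the setting used inside
#'   the learned-shrinkage pipeline).
#' @param butter_order Butterworth order (>= 1).
#' @return object of class `fbp_filter_spec`.
#' @export
fbp_filter_spec <- function(m = NULL, phi0 = 0, butter_order = 4) {
  if (!is.null(m) && m %% 2 == 0) stop("m must be odd")
  if (phi0 < 0) stop("phi0 must be nonnegative")
  structure(list(m = m, phi0 = phi0, butter_order = butter_order),
            class = "fbp_filter_spec")
}

## Effective (optionally windowed) convolution kernel at all lags
## -(n_bins-1) ... (n_bins-1), computed in the frequency domain with
## zero-padding to at least twice the detector length (no circular wrap),
## returned as the symmetric n_bins x n_bins Toeplitz filtering matrix.
fbp_filter_matrix <- function(geom, spec) {
  m <- if (is.null(spec$m)) 2L * (geom$n_bins %/% 2L) + 1L else spec$m
  key <- sprintf("filt_%d_%.8g_%d", m, spec$phi0, spec$butter_order)
  cached <- geom$cache[[key]]
  if (!is.null(cached)) return(cached)
  kap <- ram_lak_kernel(m)
  L <- 2^ceiling(log2(2 * (geom$n_bins + m)))
  half <- (m - 1) / 2
  padded <- numeric(L)
  padded[c(seq_len(half + 1), seq(L - half + 1, L))] <-
    kap[c((half + 1):m, seq_len(half))]          # circularly centered
  Fk <- Re(stats::fft(padded))
  if (spec$phi0 > 0) {
    w <- c(seq(0, L / 2), seq(L / 2 - 1, 1)) * (2 / L)  # Nyquist = 1
    Fk <- Fk * butterworth_window(w, spec$phi0, spec$butter_order)
  }
  keff <- Re(stats::fft(Fk, inverse = TRUE)) / L
  lags <- keff[seq_len(geom$n_bins)]              # lag 0 ... n_bins-1
  K <- stats::toeplitz(lags)
  geom$cache[[key]] <- K
  K
}

## One-off global scale: reconstruct a noiseless analytic disc and match the
## known attenuation level (absorbs the Delta-theta, bin-spacing and kernel
## normalization the discrete chain accumulates). Cached per geometry and
## kernel length; the Butterworth window has unit DC gain so the same scale
## serves all cutoffs.
fbp_calibration <- function(geom, m) {
  key <- sprintf("cal_%d", m)
  cached <- geom$cache[[key]]
  if (!is.null(cached)) return(cached)
  n <- geom$n
  c0 <- (n - 1) / 2
  xx <- matrix(rep(seq_len(n) - 1 - c0, each = n), n)
  rr <- sqrt(xx^2 + t(xx)^2)
  disc <- 0.2 * pmin(pmax((n / 4) - rr + 0.5, 0), 1)
  sino <- radon_forward(disc, geom)
  K <- fbp_filter_matrix(geom, fbp_filter_spec(m = m))
  recon <- back_project(sino %*% K, geom)
  cal <- sum(recon * disc) / sum(recon * recon)
  geom$cache[[key]] <- cal
  cal
}

#' Filtered back projection
#'
#' Reconstructs an attenuation image from a sinogram of line integrals:
#' per-view convolution with the Ram-Lak kernel (optionally composed with a
#' Butterworth window in the frequency domain), followed by back projection.
#' A linear operator; the global scale is calibrated once per geometry
#' against a noiseless analytic disc phantom.
#'
#' @param sino `n_views x n_bins` sinogram of line integrals.
#' @param geom a [ct_geometry()].
#' @param spec an [fbp_filter_spec()]; the default is the full-support ramp
#'   with no low-pass window.
#' @return reconstructed attenuation image (`"mu"`-flagged [ct_image()];
#'   small negative overshoots are kept, convert to HU with [mu_to_hu()]
#'   for display/evaluation).
#' @export
fbp_reconstruct <- function(sino, geom, spec = fbp_filter_spec()) {
  if (!all(dim(sino) == c(geom$n_views, geom$n_bins)))
    stop("sinogram shape does not match geometry")
  m <- if (is.null(spec$m)) 2L * (geom$n_bins %/% 2L) + 1L else spec$m
  K <- fbp_filter_matrix(geom, spec)
  cal <- fbp_calibration(geom, m)
  out <- cal * back_project(sino %*% K, geom)
  structure(out, class = c("ct_image", class(out)), units = "mu",
            pixel_size = geom$pixel_size)
}

## adjoint of fbp_reconstruct as a linear map (used by training gradients):
## v -> cal * K^T applied after forward projection of v
fbp_adjoint <- function(img, geom, spec = fbp_filter_spec()) {
  m <- if (is.null(spec$m)) 2L * (geom$n_bins %/% 2L) + 1L else spec$m
  K <- fbp_filter_matrix(geom, spec)
  cal <- fbp_calibration(geom, m)
  cal * (radon_forward(as_matrix_image(img), geom) %*% K)
}
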