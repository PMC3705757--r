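MU_WATER <- 0.19  # linear attenuation of water, 1/cm

#' Attenuation image container
#'
#' A plain numeric matrix tagged with its intensity units: `"hu"` (Hounsfield
#' units, water = 0, air = -1000) or `"mu"` (linear attenuation, 1/cm).
#'
#' @param values square numeric matrix.
#' @param units `"hu"` or `"mu"`.
#' @param pixel_size optional pixel size in cm.
#' @return the matrix with class `ct_image` and a `units` attribute.
#' @export
ct_image <- function(values, units = c("hu", "mu"), pixel_size = NULL) {
  units <- match.arg(units)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("ct_image requires a square grid")
  if (units == "mu" && any(values < 0))
    stop("attenuation values must be nonnegative in 1/cm")
  structure(values, class = c("ct_image", class(values)),
            units = units, pixel_size = pixel_size)
}

#' @export
print.ct_image <- function(x, ...) {
  cat(sprintf("ct_image %d x %d [%s], range [%.4g, %.4g]\n",
              nrow(x), ncol(x), image_units(x), min(x), max(x)))
  invisible(x)
}

image_units <- function(x) {
  u <- attr(x, "units")
  if (is.null(u)) "mu" else u
}

as_matrix_image <- function(x) {
  m <- unclass(x)
  attr(m, "units") <- NULL
  attr(m, "pixel_size") <- NULL
  as.matrix(m)
}

#' Convert Hounsfield units to linear attenuation
#'
#' Inverts the HU definition `HU = 1000 * (mu - mu_water) / (mu_water - mu_air)`
#' with `mu_water = 0.19` 1/cm and `mu_air = 0`, i.e.
#' `mu = mu_water * (1 + HU/1000)`, clamped below at 0 (sub-air HU map to
#' vacuum).
#'
#' @param image HU matrix or HU-flagged [ct_image()].
#' @return a `"mu"`-flagged [ct_image()].
#' @export
hu_to_mu <- function(image) {
  if (inherits(image, "ct_image") && image_units(image) == "mu")
    stop("image is already in 1/cm")
  m <- as_matrix_image(image)
  ct_image(pmax(MU_WATER * (1 + m / 1000), 0), units = "mu",
           pixel_size = attr(image, "pixel_size"))
}

#' Convert linear attenuation to Hounsfield units
#'
#' Exact inverse of [hu_to_mu()] on the non-clamped range:
#' `HU = 1000 * (mu - mu_water) / mu_water`.
#'
#' @param image attenuation matrix (1/cm) or `"mu"`-flagged [ct_image()].
#' @return an HU-flagged [ct_image()].
#' @export
mu_to_hu <- function(image) {
  if (inherits(image, "ct_image") && image_units(image) == "hu")
    stop("image is already in HU")
  m <- as_matrix_image(image)
  ct_image(1000 * (m - MU_WATER) / MU_WATER, units = "hu",
           pixel_size = attr(image, "pixel_size"))
}
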