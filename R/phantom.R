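## Synthetic anatomical phantoms in Hounsfield units. These play the role of
## the high-quality reference slices a clinical training set would provide:
## an elliptical soft-tissue body (~0-100 HU) with a smooth low-frequency
## intensity ramp, low-contrast organ-like inclusions (edges of <= 60 HU so
## the gradient term of the MSEg loss has targets), cortical-bone structures
## (>= 800 HU, the source of streak artifacts at low dose) and an optional
## disc lesion.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Phantom specification
#'
#' Describes a synthetic axial slice: an optional elliptical body outline
#' (air outside), a background soft-tissue level with a smooth seeded ramp,
#' a list of geometric primitives and an optional disc lesion. All intensities
#' are Hounsfield units in \[-1000, 3000\].
#'
#' @param n image side in pixels.
#' @param primitives list of primitives; each is a list with `shape` one of
#'   `"disc"`, `"ellipse"`, `"annulus"`, `center` (x, y in pixels, image
#'   center at ((n-1)/2)), `axes` (disc: radius; ellipse: semi-axes a, b;
#'   annulus: inner and outer radius), optional `angle` (radians) and `hu`.
#' @param lesion optional list with `center`, `radius` (px) and `hu`; drawn
#'   last, on top of everything else.
#' @param background_hu soft-tissue background level (HU).
#' @param body optional list with `axes` (semi-axes) and optional `center`;
#'   outside the body the image is air (-1000 HU). `NULL` fills the whole
#'   grid with the background.
#' @param ramp_amplitude amplitude (HU) of a smooth random low-frequency
#'   field added to the background inside the body.
#' @param rng_seed seed for the ramp field (phantoms are deterministic given
#'   the spec).
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(n, primitives = list(), lesion = NULL,
                         background_hu = 0, body = NULL,
                         ramp_amplitude = 0, rng_seed = 1L) {
  n <- as.integer(n)
  for (p in primitives) {
    stopifnot(p$shape %in% c("disc", "ellipse", "annulus"))
    ext <- max(p$axes)
    if (any(abs(p$center) + ext > (n - 1) / 2 + 0.5))
      stop("primitive extends outside the grid")
    if (p$hu < -1000 || p$hu > 3000) stop("HU value outside [-1000, 3000]")
  }
  if (!is.null(lesion) &&
      any(abs(lesion$center) + lesion$radius > (n - 1) / 2 + 0.5))
    stop("lesion extends outside the grid")
  structure(list(n = n, primitives = primitives, lesion = lesion,
                 background_hu = background_hu, body = body,
                 ramp_amplitude = ramp_amplitude,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

## soft-edged membership field of a primitive; d is a signed distance
## approximation (negative inside), blended over `feather` pixels. The
## default 3 px edge keeps reference images within the passband of the
## measurement geometry (~2 px reconstruction FWHM): clinical reference
## slices are themselves reconstructions and carry no frequencies the
## scanner cannot resolve.
prim_alpha <- function(xx, yy, shape, center, axes, angle = 0, feather = 3) {
  cx <- xx - center[1]; cy <- yy - center[2]
  if (angle != 0) {
    rx <- cx * cos(angle) + cy * sin(angle)
    ry <- -cx * sin(angle) + cy * cos(angle)
    cx <- rx; cy <- ry
  }
  soft <- function(d) pmin(pmax(0.5 - d / feather, 0), 1)
  if (shape == "disc") {
    soft(sqrt(cx^2 + cy^2) - axes[1])
  } else if (shape == "ellipse") {
    rho <- sqrt((cx / axes[1])^2 + (cy / axes[2])^2)
    soft((rho - 1) * min(axes))
  } else { # annulus: axes = c(r_inner, r_outer)
    r <- sqrt(cx^2 + cy^2)
    soft(r - axes[2]) * (1 - soft(r - axes[1]))
  }
}

smooth_ramp <- function(n, amplitude, seed) {
  if (amplitude <= 0) return(matrix(0, n, n))
  with_seed(seed, {
    xx <- matrix(rep(seq_len(n) - (n + 1) / 2, each = n), n) / n
    yy <- t(xx)
    f <- matrix(0, n, n)
    for (k in 1:3) {
      fr <- stats::runif(2, 0.4, 1.6)
      ph <- stats::runif(1, 0, 2 * pi)
      f <- f + stats::runif(1, 0.3, 1) *
        cos(2 * pi * (fr[1] * xx + fr[2] * yy) + ph)
    }
    f / max(abs(f)) * amplitude
  })
}

#' Render a phantom specification to an HU image
#'
#' Primitive edges are feathered over a few pixels, so projections of
#' centrally symmetric phantoms are smooth across views and low-contrast
#' edges are band limited, as in clinical reference slices (themselves
#' reconstructions with a finite point-spread function).
#'
#' @param spec a [phantom_spec()].
#' @return an HU-flagged [ct_image()].
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$n
  c0 <- (n - 1) / 2
  xx <- matrix(rep(seq_len(n) - 1 - c0, each = n), n)  # x = column offset
  yy <- matrix(rep(seq_len(n) - 1 - c0, times = n), n) # y = row offset
  bg <- spec$background_hu + smooth_ramp(n, spec$ramp_amplitude, spec$rng_seed)
  if (is.null(spec$body)) {
    img <- bg
  } else {
    ctr <- if (is.null(spec$body$center)) c(0, 0) else spec$body$center
    a <- prim_alpha(xx, yy, "ellipse", ctr, spec$body$axes)
    img <- -1000 * (1 - a) + bg * a
  }
  for (p in spec$primitives) {
    a <- prim_alpha(xx, yy, p$shape, p$center, p$axes,
                    if (is.null(p$angle)) 0 else p$angle)
    img <- img * (1 - a) + p$hu * a
  }
  if (!is.null(spec$lesion)) {
    a <- prim_alpha(xx, yy, "disc", spec$lesion$center, spec$lesion$radius,
                    feather = 1)
    img <- img * (1 - a) + spec$lesion$hu * a
  }
  ct_image(pmin(pmax(img, -1000), 3000), units = "hu")
}

#' Random anatomical phantom specification
#'
#' Draws a randomized abdomen-like slice: elliptical soft-tissue body
#' (background ~45-60 HU with a smooth +-20 HU ramp), four to five
#' low-contrast organ ellipses (contrast <= 55 HU), two cortical-bone
#' structures (an annular long-bone cross-section with marrow and a solid
#' bone disc, >= 900 HU) and optionally a lesion disc. Deterministic given
#' `seed`.
#'
#' @param n image side in pixels.
#' @param seed integer seed.
#' @param lesion optional lesion list passed through to [phantom_spec()].
#' @return a [phantom_spec()].
#' @export
random_phantom_spec <- function(n, seed = 1L, lesion = NULL) {
  with_seed(seed, {
    s <- n / 128  # scale relative to the reference grid
    body_ax <- c(stats::runif(1, 0.40, 0.45), stats::runif(1, 0.32, 0.37)) * n
    prim <- list()
    ## long bone: annulus + marrow disc, left side
    bc <- c(-stats::runif(1, 0.16, 0.22), stats::runif(1, -0.08, 0.08)) * n
    r_out <- stats::runif(1, 9, 12) * s
    prim[[1]] <- list(shape = "annulus", center = bc,
                      axes = c(r_out * stats::runif(1, 0.45, 0.6), r_out),
                      hu = stats::runif(1, 1000, 1400))
    prim[[2]] <- list(shape = "disc", center = bc, axes = r_out * 0.4,
                      hu = stats::runif(1, 150, 250))
    ## solid bone, right side
    prim[[3]] <- list(shape = "disc",
                      center = c(stats::runif(1, 0.16, 0.22),
                                 stats::runif(1, -0.08, 0.08)) * n,
                      axes = stats::runif(1, 6, 9) * s,
                      hu = stats::runif(1, 900, 1300))
    ## low-contrast organs
    n_org <- sample(4:5, 1)
    for (k in seq_len(n_org)) {
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- stats::runif(1, 0.08, 0.55)
      ctr <- c(cos(ang) * body_ax[1], sin(ang) * body_ax[2]) * rad
      ax <- sort(stats::runif(2, 4, 14) * s, decreasing = TRUE)
      ## keep inside the body ellipse
      rho <- sqrt((ctr[1] / body_ax[1])^2 + (ctr[2] / body_ax[2])^2)
      if (rho * max(body_ax) + max(ax) > 0.92 * min(body_ax))
        ax <- ax * 0.5
      prim[[length(prim) + 1]] <-
        list(shape = "ellipse", center = ctr, axes = ax,
             angle = stats::runif(1, 0, pi),
             hu = 52 + sample(c(-1, 1), 1) * stats::runif(1, 20, 55))
    }
    phantom_spec(n, primitives = prim, lesion = lesion,
                 background_hu = stats::runif(1, 45, 60),
                 body = list(axes = body_ax),
                 ramp_amplitude = 20,
                 rng_seed = sample.int(1e6, 1))
  })
}
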