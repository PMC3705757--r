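## Patch-based learned shrinkage. A d x d unitary 2D-DCT dictionary analyses
## overlapping patches; each of the d^2 coefficient bands has its own
## antisymmetric piecewise-linear shrinkage function with K positive knots
## (evenly spaced over the band's training dynamic range). The slice
## transform writes the shrinkage output as a sparse-matrix product that is
## linear in the knot values p, which is what makes the training gradient
## cheap.

#' Unitary 2D DCT patch dictionary
#'
#' Builds the `d^2` orthonormal separable cosine atoms of size `d x d`.
#' Column 1 of the synthesis matrix is the constant (DC) atom with value
#' `1/d`.
#'
#' @param d patch side in pixels (>= 2).
#' @return object of class `patch_dictionary` with elements `d` and `D`
#'   (`d^2 x d^2` synthesis matrix whose columns are vectorized atoms;
#'   analysis is `t(D)`).
#' @export
dct_dictionary <- function(d) {
  d <- as.integer(d)
  if (d < 2) stop("patch side must be at least 2")
  k <- 0:(d - 1)
  C <- sqrt(2 / d) * cos(pi * outer(k, 2 * k + 1) / (2 * d))
  C[1, ] <- sqrt(1 / d)
  W <- kronecker(C, C)    # analysis: vec(C P C^T) = W vec(P)
  structure(list(d = d, D = t(W)), class = "patch_dictionary")
}

#' @export
print.patch_dictionary <- function(x, ...) {
  cat(sprintf("Unitary 2D DCT dictionary: %d atoms of %d x %d\n",
              x$d^2, x$d, x$d))
  invisible(x)
}

## Precomputed patch index map: linear indices of every d x d window at the
## stride lattice plus windows flush with the lower/right borders, and the
## per-pixel coverage counts used for overlap averaging.
patch_map <- function(dim, d, stride = 1) {
  nr <- dim[1]; nc <- dim[2]
  if (nr < d || nc < d) stop("signal smaller than a patch")
  if (stride < 1 || stride > d) stop("stride must be in [1, d]")
  starts <- function(n) unique(c(seq(1L, n - d + 1L, by = stride), n - d + 1L))
  sr <- starts(nr); sc <- starts(nc)
  base <- outer(sr - 1L, (sc - 1L) * nr, "+") + 1L
  offs <- as.vector(outer(0:(d - 1L), (0:(d - 1L)) * nr, "+"))
  idx <- outer(offs, as.vector(base), "+")
  counts <- numeric(nr * nc)
  tb <- table(idx)
  counts[as.integer(names(tb))] <- as.vector(tb)
  if (any(counts == 0)) stop("patch lattice leaves uncovered pixels")
  list(dim = dim, d = d, stride = stride, idx = idx, counts = counts,
       n_patches = ncol(idx))
}

#' Extract overlapping patches
#'
#' Collects all `d x d` windows on the stride lattice, plus windows flush
#' with the right/bottom borders so every pixel is covered at any stride.
#'
#' @param signal 2D numeric matrix, at least `d x d`.
#' @param d patch side.
#' @param stride lattice step in pixels, `1 <= stride <= d`.
#' @return list with `patches` (`d^2 x n_patches` matrix, columns are
#'   vectorized windows) and `map` (the index map consumed by
#'   [reassemble_patches()]).
#' @export
extract_patches <- function(signal, d, stride = 1) {
  map <- patch_map(dim(signal), d, stride)
  list(patches = matrix(signal[map$idx], nrow = d * d), map = map)
}

#' Reassemble patches by overlap averaging
#'
#' Each pixel of the output is the average of its value over all patches
#' containing it (the `M_E^-1 sum E_k^T` normalization).
#'
#' @param patches `d^2 x n_patches` matrix.
#' @param map index map from [extract_patches()].
#' @return matrix of the original signal shape.
#' @export
reassemble_patches <- function(patches, map) {
  acc <- numeric(prod(map$dim))
  s <- rowsum(as.vector(patches), group = as.vector(map$idx))
  acc[as.integer(rownames(s))] <- s
  matrix(acc / map$counts, nrow = map$dim[1])
}

#' Per-band knot domains from training coefficients
#'
#' For band i the knots are `K` evenly spaced points from `r_i/K` to `r_i`,
#' where `r_i` is the largest coefficient magnitude observed for that band
#' over the training data. An all-zero band falls back to `r_i = 1`.
#'
#' @param coeffs `n_bands x n_coefficients` matrix of training coefficients
#'   (concatenate items column-wise for a training set).
#' @param K knots per band (>= 2); default 20.
#' @return `n_bands x K` matrix of strictly increasing positive knots.
#' @export
build_knot_domains <- function(coeffs, K = 20) {
  if (K < 2) stop("K must be at least 2")
  r <- apply(abs(coeffs), 1, max)
  r[r == 0] <- 1
  outer(r / K, seq_len(K))
}

#' Shrinkage parameter set
#'
#' @param q `n_bands x K` knot abscissae (strictly increasing, positive).
#' @param p `n_bands x K` knot ordinates. `p = q` is the identity map.
#' @return object of class `shrinkage_params`.
#' @export
shrinkage_params <- function(q, p = q) {
  q <- as.matrix(q); p <- as.matrix(p)
  if (!all(dim(q) == dim(p))) stop("q and p must have the same shape")
  if (any(q[, 1] <= 0) || any(t(apply(q, 1, diff)) <= 0))
    stop("knot domains must be strictly increasing and positive")
  structure(list(q = q, p = p, n_bands = nrow(q), K = ncol(q)),
            class = "shrinkage_params")
}

#' @export
print.shrinkage_params <- function(x, ...) {
  dev <- sqrt(sum((x$p - x$q)^2)) / sqrt(sum(x$q^2))
  cat(sprintf("Shrinkage parameters: %d bands x %d knots (rel. deviation from identity %.3g)\n",
              x$n_bands, x$K, dev))
  invisible(x)
}

## Interval membership and (signed) linear weights of coefficients on their
## band's knot grid; the common core of shrinkage evaluation, the slice
## transform and the training gradient. Knot index 0 stands for the fixed
## origin S(0) = 0; beyond the last knot the final segment is extended
## linearly. The coefficient's sign is folded into the weights, so
## S(coeffs) = w1 * p[band, i1] + w2 * p[band, i2] directly.
slt_weights <- function(coeffs, q) {
  K <- ncol(q)
  band <- as.vector(row(coeffs))
  v <- as.vector(coeffs)
  sgn <- sign(v)
  rel <- abs(v) / q[, 1][band]
  j0 <- floor(rel)
  inter <- j0 < K
  i1 <- integer(length(v)); i2 <- integer(length(v))
  w1 <- numeric(length(v)); w2 <- numeric(length(v))
  w <- rel[inter] - j0[inter]
  i1[inter] <- as.integer(j0[inter]); w1[inter] <- 1 - w
  i2[inter] <- i1[inter] + 1L;        w2[inter] <- w
  if (any(!inter)) {
    e <- rel[!inter] - K
    i1[!inter] <- K - 1L; w1[!inter] <- -e
    i2[!inter] <- K;      w2[!inter] <- 1 + e
  }
  list(band = band, i1 = i1, w1 = w1 * sgn, i2 = i2, w2 = w2 * sgn,
       K = K, n_bands = nrow(q))
}

slt_eval <- function(w, p) {
  v1 <- numeric(length(w$i1))
  k1 <- w$i1 > 0L
  v1[k1] <- p[cbind(w$band[k1], w$i1[k1])]
  v2 <- p[cbind(w$band, w$i2)]
  w$w1 * v1 + w$w2 * v2
}

## accumulate d Loss / d p given upstream sensitivities of the shrunk
## coefficients (same layout as coeffs)
slt_grad_p <- function(w, upstream) {
  g <- numeric(w$n_bands * w$K)
  u <- as.vector(upstream)
  keep1 <- w$i1 > 0L
  lin <- c(w$band[keep1] + (w$i1[keep1] - 1L) * w$n_bands,
           w$band + (w$i2 - 1L) * w$n_bands)
  val <- c(w$w1[keep1] * u[keep1], w$w2 * u)
  s <- rowsum(val, group = lin)
  g[as.integer(rownames(s))] <- s
  matrix(g, nrow = w$n_bands)
}

#' Apply per-band shrinkage functions to coefficients
#'
#' Each coefficient `x` in band `i` is mapped by the antisymmetric piecewise
#' linear function through `(0, 0)` and the band's knots `(q_ij, p_ij)`:
#' `S(x) = sign(x) * S_i(|x|)`. Beyond the last knot the final segment is
#' extended linearly.
#'
#' @param coeffs `n_bands x n_coefficients` matrix (bands in rows).
#' @param params a [shrinkage_params()] with matching band count.
#' @return matrix of the same shape.
#' @export
apply_shrinkage <- function(coeffs, params) {
  coeffs <- as.matrix(coeffs)
  if (nrow(coeffs) != params$n_bands)
    stop("band count does not match shrinkage parameters")
  matrix(slt_eval(slt_weights(coeffs, params$q), params$p),
         nrow = nrow(coeffs))
}

#' Slice transform of one coefficient band
#'
#' Builds the sparse matrix `U` (one row per coefficient, one column per
#' knot, at most two nonzeros per row) with `U %*% q_i` reproducing the
#' coefficients exactly and `U %*% p_i` equal to the direct shrinkage
#' evaluation for any knot values `p_i`.
#'
#' @param coeffs numeric vector of one band's coefficients.
#' @param q_i numeric vector of the band's knots (evenly spaced, positive).
#' @return a sparse `length(coeffs) x length(q_i)` matrix (class `dgCMatrix`).
#' @export
slice_transform <- function(coeffs, q_i) {
  w <- slt_weights(matrix(coeffs, nrow = 1), matrix(q_i, nrow = 1))
  n <- length(coeffs)
  keep1 <- w$i1 > 0L
  Matrix::sparseMatrix(
    i = c(which(keep1), seq_len(n)),
    j = c(w$i1[keep1], w$i2),
    x = c(w$w1[keep1], w$w2),
    dims = c(n, length(q_i)))
}

#' Patchwise learned-shrinkage filter
#'
#' The estimator `M_E^-1 sum_k E_k^T D S_p D^T E_k y`: extract overlapping
#' patches, analyse in the DCT dictionary, shrink each band, synthesize, and
#' average the overlaps.
#'
#' @param signal 2D matrix.
#' @param dict a [dct_dictionary()].
#' @param params a [shrinkage_params()] with `d^2` bands.
#' @param stride patch lattice step (default 1, maximal overlap).
#' @return filtered matrix, same shape as `signal`.
#' @export
shrinkage_filter <- function(signal, dict, params, stride = 1) {
  ep <- extract_patches(signal, dict$d, stride)
  coeffs <- crossprod(dict$D, ep$patches)
  reassemble_patches(dict$D %*% apply_shrinkage(coeffs, params), ep$map)
}
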