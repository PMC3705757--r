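## Shared fixtures, memoized across test files (building the sparse system
## matrix for a geometry is the expensive part).

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

test_geom <- function(n) memo(paste0("geom", n), ct_geometry(n))

## band-limited centrally symmetric disc (edge smoothed over ~2 px so the
## phantom is representable on the grid at any view angle)
smooth_disc <- function(n, radius, value) {
  c0 <- (n - 1) / 2
  xx <- matrix(rep(seq_len(n) - 1 - c0, each = n), n)
  rr <- sqrt(xx^2 + t(xx)^2)
  value / (1 + exp((rr - radius) * 2))
}

test_phantom <- function(n, seed = 7) {
  memo(paste0("phantom", n, "_", seed),
       make_phantom(random_phantom_spec(n, seed)))
}

## small training set + frozen knot domains used by the training tests
small_train_fixture <- function() {
  memo("small_train", {
    geom <- test_geom(32)
    model <- scan_model()
    tset <- ct_training_set(list(test_phantom(32, 7)), geom, model, seed = 11)
    dict <- dct_dictionary(11)
    z <- omega_forward(tset$items[[1]]$y, model)
    coeffs <- crossprod(dict$D, extract_patches(z, 11, 2)$patches)
    q <- build_knot_domains(coeffs, 20)
    list(geom = geom, model = model, tset = tset, dict = dict, q = q,
         stride = 2)
  })
}
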