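## Directory-based artifact container: 32-bit TIFF images (affine-scaled to
## [0, 1] with a JSON sidecar recording slope/intercept and units), CSV
## arrays and JSON metadata. Every container carries a provenance block.

#' Write an image as 32-bit TIFF with a scaling sidecar
#'
#' TIFF stores values in \[0, 1\]; the affine mapping back to physical units
#' (and the unit flag) is written to `<path>.json`.
#'
#' @param img matrix or [ct_image()].
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(img, path) {
  m <- as_matrix_image(img)
  lo <- min(m); hi <- max(m)
  slope <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF((m - lo) / slope, path, bits.per.sample = 32L)
  jsonlite::write_json(list(slope = slope, intercept = lo,
                            units = image_units(img), dim = dim(m)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image written by [write_image_tiff()]
#'
#' @param path `.tif` path with its `.json` sidecar.
#' @return a [ct_image()].
#' @export
read_image_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- tiff::readTIFF(path) * meta$slope + meta$intercept
  ct_image(m, units = meta$units)
}

write_array_csv <- function(x, path) {
  utils::write.table(x, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

read_array_csv <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(m) <- NULL
  m
}

geometry_meta <- function(geom) {
  list(n = geom$n, n_views = geom$n_views, n_bins = geom$n_bins,
       bin_spacing = geom$bin_spacing, pixel_size = geom$pixel_size)
}

geometry_from_meta <- function(m) {
  ct_geometry(m$n, oversampling = 1 / m$bin_spacing, n_views = m$n_views,
              pixel_size = m$pixel_size)
}

provenance <- function(extra = list()) {
  c(list(package = "shrinkct",
         version = as.character(utils::packageVersion("shrinkct")),
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")), extra)
}

#' Persist a fitted model as a directory
#'
#' Writes `model.json` (geometry, scan model, configuration, seeds,
#' provenance), CSV arrays for the knot domains and values of both stages,
#' and the training objective traces as CSV.
#'
#' @param fit a fitted [shrinkct()] model.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_shrinkct <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- provenance(list(
    geometry = geometry_meta(fit$geom),
    scan_model = fit$model[c("lambda0", "sigma_n", "dark")],
    config = unclass(fit$config),
    gamma = fit$gamma, gamma_I = fit$gamma_I,
    d = fit$dict$d, K = fit$stage1$K,
    stride = fit$stride, stride_image = fit$stride_image,
    seed = fit$seed, n_train = fit$n_train))
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  write_array_csv(fit$stage1$q, file.path(dir, "stage1_q.csv"))
  write_array_csv(fit$stage1$p, file.path(dir, "stage1_p.csv"))
  write_array_csv(fit$stage2$q, file.path(dir, "stage2_q.csv"))
  write_array_csv(fit$stage2$p, file.path(dir, "stage2_p.csv"))
  for (st in c("stage1", "stage2")) {
    utils::write.csv(data.frame(iteration = seq_along(fit$logs[[st]]),
                                objective = fit$logs[[st]]),
                     file.path(dir, paste0("trace_", st, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Load a model saved by [save_shrinkct()]
#'
#' @param dir model directory.
#' @return an object of class `shrinkct` (without the training-set
#'   reconstructions).
#' @export
load_shrinkct <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  logs <- lapply(c(stage1 = "stage1", stage2 = "stage2"), function(st) {
    utils::read.csv(file.path(dir, paste0("trace_", st, ".csv")))$objective
  })
  structure(list(
    stage1 = shrinkage_params(read_array_csv(file.path(dir, "stage1_q.csv")),
                              read_array_csv(file.path(dir, "stage1_p.csv"))),
    stage2 = shrinkage_params(read_array_csv(file.path(dir, "stage2_q.csv")),
                              read_array_csv(file.path(dir, "stage2_p.csv"))),
    dict = dct_dictionary(meta$d),
    geom = geometry_from_meta(meta$geometry),
    model = scan_model(meta$scan_model$lambda0, meta$scan_model$sigma_n,
                       meta$scan_model$dark),
    config = quality_config(meta$config$mu, meta$config$delta,
                            unlist(meta$config$hu_window),
                            meta$config$w_threshold),
    gamma = meta$gamma, gamma_I = meta$gamma_I,
    stride = meta$stride, stride_image = meta$stride_image,
    seed = meta$seed, n_train = meta$n_train,
    logs = logs, stage1_train = NULL, call = NULL), class = "shrinkct")
}

#' Simulate a phantom/measurement container
#'
#' Generates phantoms, noiseless sinograms and noisy counts, and writes them
#' with full provenance (seeds, dose, geometry) to a directory.
#'
#' @param config list with elements `out_dir`, and optionally `n` (128),
#'   `n_phantoms` (9), `lambda0` (1.5e5), `sigma_n` (5), `rng_seed` (1).
#' @return the container directory, invisibly.
#' @export
run_simulate <- function(config) {
  n <- config$n %||% 128
  n_ph <- config$n_phantoms %||% 9
  seed <- config$rng_seed %||% 1L
  model <- scan_model(config$lambda0 %||% 1.5e5, config$sigma_n %||% 5)
  geom <- ct_geometry(n)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(n_ph)) {
    ph <- make_phantom(random_phantom_spec(n, seed = seed + i))
    sino <- radon_forward(hu_to_mu(ph), geom)
    y <- simulate_counts(sino, model, seed = seed + 1000 + i)
    write_image_tiff(ph, file.path(config$out_dir,
                                   sprintf("phantom_%02d.tif", i)))
    write_array_csv(sino, file.path(config$out_dir,
                                    sprintf("sinogram_%02d.csv", i)))
    write_array_csv(y, file.path(config$out_dir,
                                 sprintf("counts_%02d.csv", i)))
  }
  jsonlite::write_json(
    provenance(list(n = n, n_phantoms = n_ph, rng_seed = seed,
                    lambda0 = model$lambda0, sigma_n = model$sigma_n,
                    geometry = geometry_meta(geom))),
    file.path(config$out_dir, "provenance.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(config$out_dir)
}

#' Train a model from a simulated container
#'
#' @param config list with `container` (from [run_simulate()]), `model_dir`,
#'   and optional training hyperparameters (`mu`, `gamma`, `gamma_I`, `d`,
#'   `K`, `stride`, `max_iter`).
#' @return the fitted model, invisibly.
#' @export
run_train <- function(config) {
  prov <- jsonlite::read_json(file.path(config$container, "provenance.json"),
                              simplifyVector = TRUE)
  phantoms <- lapply(seq_len(prov$n_phantoms), function(i) {
    read_image_tiff(file.path(config$container,
                              sprintf("phantom_%02d.tif", i)))
  })
  fit <- shrinkct(
    phantoms,
    geom = geometry_from_meta(prov$geometry),
    model = scan_model(prov$lambda0, prov$sigma_n),
    config = quality_config(mu = config$mu %||% 100),
    gamma = config$gamma %||% 1e-4, gamma_I = config$gamma_I %||% 250,
    d = config$d %||% 11, K = config$K %||% 20,
    stride = config$stride %||% 2,
    max_iter = config$max_iter %||% c(100, 40),
    seed = prov$rng_seed)
  save_shrinkct(fit, config$model_dir)
  invisible(fit)
}

#' Reconstruct a container's measurements with the requested methods
#'
#' @param config list with `container`, `model_dir`, `out_dir`, `item`
#'   (index of the scan to reconstruct, default 1) and `methods` (subset of
#'   `"fbp"`, `"stage1"`, `"full"`, `"atm"`, `"pwls"`).
#' @return list of quality reports, invisibly; images and a JSON report are
#'   written to `out_dir`.
#' @export
run_reconstruct <- function(config) {
  if (!dir.exists(config$model_dir)) stop("model directory not found")
  fit <- load_shrinkct(config$model_dir)
  prov <- jsonlite::read_json(file.path(config$container, "provenance.json"),
                              simplifyVector = TRUE)
  i <- config$item %||% 1L
  y <- read_array_csv(file.path(config$container,
                                sprintf("counts_%02d.csv", i)))
  ref <- read_image_tiff(file.path(config$container,
                                   sprintf("phantom_%02d.tif", i)))
  methods <- config$methods %||% c("fbp", "stage1", "full")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  recs <- list()
  for (m in methods) {
    recs[[m]] <- switch(m,
      fbp = mu_to_hu(fbp_reconstruct(counts_to_sinogram(y, fit$model),
                                     fit$geom,
                                     fbp_filter_spec(phi0 = config$fbp_phi0 %||% 0.7))),
      stage1 = predict(fit, y, stage = "stage1"),
      full = predict(fit, y, stage = "full"),
      atm = mu_to_hu(fbp_reconstruct(
        counts_to_sinogram(atm_filter(y, atm_params()), fit$model),
        fit$geom, fbp_filter_spec(phi0 = config$fbp_phi0 %||% 0.7))),
      pwls = pwls_reconstruct(y, pwls_config(), fit$model, fit$geom),
      stop("unknown method: ", m))
    write_image_tiff(recs[[m]], file.path(config$out_dir,
                                          paste0("recon_", m, ".tif")))
  }
  reports <- lapply(recs, function(r) quality_report(ref, r, fit$config))
  jsonlite::write_json(provenance(list(item = i, reports = reports)),
                       file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(reports)
}

#' Run a scripted experiment
#'
#' Dispatches on `config$experiment`: `"dose_sweep"`
#' ([experiment_dose_reduction()]), `"lesion"` ([experiment_lesion()]),
#' `"lir"` ([experiment_lir()]) or `"cutoff_sweep"`
#' ([experiment_cutoff_sweep()]). Results are written as JSON to
#' `config$out_dir` when given.
#'
#' @param config list with `experiment`, `model_dir` (except cutoff sweep),
#'   optional `out_dir` and experiment-specific fields.
#' @return the experiment result, invisibly.
#' @export
run_experiment <- function(config) {
  seed <- config$rng_seed %||% 1L
  res <- switch(config$experiment,
    cutoff_sweep = experiment_cutoff_sweep(seed = seed),
    dose_sweep = {
      fit <- load_shrinkct(config$model_dir)
      heldout <- lapply(seq_len(config$n_heldout %||% 2), function(i)
        make_phantom(random_phantom_spec(fit$geom$n, seed = seed + 100 + i)))
      tune_ph <- lapply(1:3, function(i)
        make_phantom(random_phantom_spec(fit$geom$n, seed = fit$seed + i)))
      experiment_dose_reduction(fit, heldout, tune_phantoms = tune_ph,
                                seed = seed)
    },
    lesion = {
      fit <- load_shrinkct(config$model_dir)
      experiment_lesion(fit, lambda0 = config$lambda0 %||% 7e4, seed = seed)
    },
    lir = {
      fit <- load_shrinkct(config$model_dir)
      experiment_lir(fit, n_spikes = config$n_spikes %||% 100, seed = seed)
    },
    stop("unknown experiment: ", config$experiment))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    serializable <- switch(config$experiment,
      cutoff_sweep = res[c("sweep", "argmin_mse", "argmin_Q")],
      dose_sweep = res[c("factor_mseg", "factor_snr", "pipeline",
                         "fbp_curve")],
      lesion = list(stats = res$stats),
      lir = lapply(res, function(s) list(mean_fwhm = s$mean_fwhm,
                                         fwhm = s$fwhm)))
    jsonlite::write_json(provenance(list(experiment = config$experiment,
                                         result = serializable)),
                         file.path(config$out_dir,
                                   paste0(config$experiment, ".json")),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  invisible(res)
}
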