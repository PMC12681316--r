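#' Write a signal patch as NIfTI plus a JSON sidecar
#'
#' Stores the four normalized signal maps as a single 4D NIfTI volume
#' (`n x n x 1 x 4`, voxel dimensions from the patch geometry) and the
#' geometry, provenance, seed, and degenerate-voxel flags in a JSON sidecar
#' next to it. Degenerate voxels are written as zero in the image and
#' restored to `NA` on reading via the sidecar flags.
#'
#' @param patch a `signal_patch`.
#' @param path_prefix output path without extension; writes
#'   `<prefix>.nii.gz` and `<prefix>.json`.
#' @return The two paths, invisibly.
#' @export
write_patch <- function(patch, path_prefix) {
  stopifnot(inherits(patch, "signal_patch"))
  g <- patch$geometry
  n <- g$n_voxels
  arr <- array(0, dim = c(n, n, 1, 4))
  sig <- patch$signals
  sig[is.na(sig)] <- 0
  arr[, , 1, ] <- sig
  img <- RNifti::asNifti(arr, pixdim = c(g$voxel_size, g$voxel_size,
                                         g$slice_thickness, 1))
  nii <- paste0(path_prefix, ".nii.gz")
  RNifti::writeNifti(img, nii)
  side <- paste0(path_prefix, ".json")
  jsonlite::write_json(list(
    n_voxels = g$n_voxels, voxel_size = g$voxel_size,
    slice_thickness = g$slice_thickness, subdivision = g$subdivision,
    exclusion_radius = g$exclusion_radius,
    provenance = patch$provenance, seed = patch$seed,
    degenerate = which(patch$degenerate)), side, auto_unbox = TRUE)
  invisible(c(nii, side))
}

#' Read a signal patch written by [write_patch()]
#'
#' @param path_prefix path prefix used when writing.
#' @return A `signal_patch`.
#' @export
read_patch <- function(path_prefix) {
  img <- RNifti::readNifti(paste0(path_prefix, ".nii.gz"))
  meta <- jsonlite::read_json(paste0(path_prefix, ".json"),
                              simplifyVector = TRUE)
  geom <- patch_geometry(meta$n_voxels, meta$voxel_size,
                         meta$slice_thickness, meta$subdivision,
                         meta$exclusion_radius)
  n <- geom$n_voxels
  degen <- matrix(FALSE, n, n)
  if (length(meta$degenerate)) degen[meta$degenerate] <- TRUE
  arr <- array(as.numeric(img), dim = c(n, n, 4),
               dimnames = list(NULL, NULL, c("s_a1", "s_a2", "s_b1", "s_b2")))
  for (k in 1:4) arr[, , k][degen] <- NA_real_
  structure(list(signals = arr, degenerate = degen, geometry = geom,
                 provenance = meta$provenance,
                 seed = if (is.null(meta$seed)) NULL else meta$seed,
                 raw = NULL),
            class = "signal_patch")
}

#' Write a signal patch as plain CSV
#'
#' Long-format text serialization (one row per voxel) used for fixtures and
#' interchange: voxel indices, the four normalized signals, and the
#' degenerate flag.
#'
#' @param patch a `signal_patch`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_patch_csv <- function(patch, path) {
  stopifnot(inherits(patch, "signal_patch"))
  flat <- .flatten_patch(patch)
  g <- patch$geometry
  n <- g$n_voxels
  df <- data.frame(ix = rep(seq_len(n), times = n),
                   iy = rep(seq_len(n), each = n),
                   s_a1 = flat$signals[, 1], s_a2 = flat$signals[, 2],
                   s_b1 = flat$signals[, 3], s_b2 = flat$signals[, 4],
                   degenerate = flat$degenerate)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_voxels=%d voxel_size=%g slice_thickness=%g subdivision=%d exclusion_radius=%g provenance=%s",
                     n, g$voxel_size, g$slice_thickness, g$subdivision,
                     g$exclusion_radius, patch$provenance), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a signal patch written by [write_patch_csv()]
#'
#' @param path CSV path.
#' @return A `signal_patch`.
#' @export
read_patch_csv <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(sub("^# ", "", lines[1]), " ")[[1]]
  kv <- do.call(rbind, strsplit(hdr, "="))
  meta <- stats::setNames(as.list(kv[, 2]), kv[, 1])
  df <- utils::read.csv(text = lines[-1])
  geom <- patch_geometry(as.integer(meta$n_voxels),
                         as.numeric(meta$voxel_size),
                         as.numeric(meta$slice_thickness),
                         as.integer(meta$subdivision),
                         as.numeric(meta$exclusion_radius))
  n <- geom$n_voxels
  m <- as.matrix(df[, c("s_a1", "s_a2", "s_b1", "s_b2")])
  .as_signal_patch(m, as.logical(df$degenerate), geom,
                   provenance = meta$provenance)
}

#' Extract and normalize a measurement patch from four images
#'
#' Reads the four co-registered da-hdrAFI magnitude images, extracts an
#' `n x n` voxel patch centered on an approximate wire location (the one
#' manual step of the workflow; the precise wire position is fitted), and
#' normalizes the four signals of each voxel. Voxels where all four signals
#' are zero are flagged degenerate.
#'
#' @param paths character vector of 4 NIfTI paths, in the order
#'   `s_a1, s_a2, s_b1, s_b2`.
#' @param center_hint approximate wire location in 1-based voxel indices
#'   `c(i, j)` of the image grid.
#' @param geom a [patch_geometry()].
#' @return A `signal_patch` with provenance `"acquired"`.
#' @export
read_patch_images <- function(paths, center_hint, geom = patch_geometry()) {
  stopifnot(length(paths) == 4, length(center_hint) == 2)
  imgs <- lapply(paths, RNifti::readNifti)
  dims <- lapply(imgs, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("images are not on the same grid")
  d <- dims[[1]]
  n <- geom$n_voxels
  i0 <- round(center_hint[1]) - floor(n / 2)
  j0 <- round(center_hint[2]) - floor(n / 2)
  if (i0 < 1 || j0 < 1 || i0 + n - 1 > d[1] || j0 + n - 1 > d[2])
    stop("patch exceeds image bounds at the given center hint")
  raw <- matrix(NA_real_, n * n, 4)
  for (k in 1:4) {
    sl <- if (length(d) >= 3) imgs[[k]][i0:(i0 + n - 1), j0:(j0 + n - 1), 1]
          else imgs[[k]][i0:(i0 + n - 1), j0:(j0 + n - 1)]
    raw[, k] <- abs(as.vector(sl))
  }
  nrm <- sqrt(rowSums(raw^2))
  if (all(nrm == 0)) stop("all-zero patch: wrong location or empty images")
  degen <- nrm == 0
  norm <- raw / nrm
  norm[degen, ] <- NA_real_
  .as_signal_patch(norm, degen, geom, provenance = "acquired")
}

#' Read a run configuration
#'
#' Loads a YAML or JSON configuration and materializes the typed objects:
#' sequence parameters, patch geometry, pulse and dictionary settings, and
#' fit configuration. Missing sections fall back to package defaults, so a
#' minimal config is valid.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON config file.
#' @return A list of class `run_config` with elements `seq_par`, `geom`,
#'   `pulse`, `t1`, `lambda_max`, `lambda_step`, `fit` (options passed to
#'   [fit_config()]), `seed`, and `raw` (the unparsed list).
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  take <- function(x, defaults) {
    args <- defaults
    for (nm in names(x)) args[[nm]] <- x[[nm]]
    args
  }
  seq_par <- do.call(sequence_params, take(raw$sequence, list()))
  geom <- do.call(patch_geometry, take(raw$geometry, list()))
  pulse <- do.call(pulse_spec, take(raw$pulse, list()))
  dict_cfg <- take(raw$dictionary,
                   list(t1 = 1000, lambda_max = 30, lambda_step = 0.01,
                        n_positions = 201L, z_extent = 2))
  structure(list(seq_par = seq_par, geom = geom, pulse = pulse,
                 t1 = dict_cfg$t1, lambda_max = dict_cfg$lambda_max,
                 lambda_step = dict_cfg$lambda_step,
                 n_positions = dict_cfg$n_positions,
                 z_extent = dict_cfg$z_extent,
                 fit = raw$fit,
                 seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed),
                 raw = raw),
            class = "run_config")
}

# Build the dictionary described by a run_config.
.config_dictionary <- function(cfg) {
  build_slice_dictionary(cfg$seq_par, cfg$pulse, cfg$t1,
                         lambda_grid = seq(0, cfg$lambda_max,
                                           by = cfg$lambda_step),
                         n_positions = cfg$n_positions,
                         z_extent = cfg$z_extent)
}

#' Run one step of the current-measurement workflow
#'
#' Thin orchestration over the package's functions, mirroring the intended
#' scanner-side workflow: build the signal dictionary, simulate or read a
#' patch, fit the wire current, calibrate the heating constant from paired
#' (current, temperature) observations, predict heating, and derive the
#' B1rms exposure limit. All artifacts are plain files (JSON, CSV, NIfTI)
#' and every stochastic step records its seed.
#'
#' @param config a `run_config` from [read_run_config()], or a path to one.
#' @param command one of `"build-dict"`, `"simulate"`, `"fit"`,
#'   `"calibrate"`, `"predict"`, `"limit"`.
#' @param out_dir directory for output artifacts.
#' @return A list of output paths and key results, invisibly.
#' @export
run_workflow <- function(config,
                         command = c("build-dict", "simulate", "fit",
                                     "calibrate", "predict", "limit"),
                         out_dir = ".") {
  command <- match.arg(command)
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  raw <- config$raw
  res <- switch(command,
    "build-dict" = {
      dict <- .config_dictionary(config)
      p <- file.path(out_dir, "dictionary.csv")
      write_dictionary(dict, p)
      list(dictionary = p)
    },
    "simulate" = {
      tr <- raw$truth
      if (is.null(tr)) stop("simulate requires a 'truth' config section")
      params <- wire_model_params(
        i_rms = tr$i_rms,
        phi_j_prime = if (is.null(tr$phi_j_prime)) 0 else tr$phi_j_prime,
        geometry = wire_geometry(
          xi = if (is.null(tr$xi)) 0 else tr$xi,
          theta = if (is.null(tr$theta)) 0 else tr$theta,
          x0 = if (is.null(tr$x0)) 0 else tr$x0,
          y0 = if (is.null(tr$y0)) 0 else tr$y0),
        background = background_field(
          lambda_b = if (is.null(tr$lambda_b)) 1 else tr$lambda_b))
      dict <- .config_dictionary(config)
      spec <- scene_spec(params, config$geom, config$seq_par, config$t1,
                         noise_sigma = raw$noise_sigma,
                         noise_model = if (is.null(raw$noise_model))
                           "gaussian" else raw$noise_model,
                         seed = config$seed)
      gen <- generate_patch(spec, dict)
      prefix <- file.path(out_dir, "patch")
      write_patch(gen$patch, prefix)
      list(patch_prefix = prefix, noise_sd = gen$noise_sd)
    },
    "fit" = {
      dict <- .config_dictionary(config)
      patch <- if (!is.null(raw$patch_prefix)) read_patch(raw$patch_prefix)
               else read_patch_images(unlist(raw$images),
                                      unlist(raw$center_hint), config$geom)
      hint <- if (is.null(raw$position_hint)) c(0, 0)
              else unlist(raw$position_hint)
      fit_opts <- config$fit
      cfg_args <- list(bounds = default_fit_bounds(hint,
                                                   config$geom$voxel_size),
                       seed = config$seed)
      for (nm in names(fit_opts)) cfg_args[[nm]] <- fit_opts[[nm]]
      fit <- fit_patch(patch, config$seq_par, dict, config$geom,
                       do.call(fit_config, cfg_args))
      p <- file.path(out_dir, "fit_result.json")
      jsonlite::write_json(list(
        i_rms_mA = 1000 * fit$params$i_rms,
        b1_rms_ref_uT = config$seq_par$b1_rms_seq,
        phi_j_prime = fit$params$phi_j_prime,
        xi = fit$params$geometry$xi, theta = fit$params$geometry$theta,
        x0 = fit$params$geometry$x0, y0 = fit$params$geometry$y0,
        lambda_b = fit$params$background$lambda_b,
        lambda_b_dx = fit$params$background$lambda_b_dx,
        lambda_b_dy = fit$params$background$lambda_b_dy,
        rms_residual = fit$rms_residual,
        n_masked_voxels = fit$n_masked_voxels,
        identifiable = fit$identifiable, seed = config$seed),
        p, auto_unbox = TRUE, digits = NA)
      list(fit = fit, result = p)
    },
    "calibrate" = {
      obs <- utils::read.csv(raw$observations)
      cal <- fit_cimplant(obs, b1_rms_ref = config$seq_par$b1_rms_seq,
                          slice_distance = raw$slice_distance,
                          implant_id = if (is.null(raw$implant_id))
                            "implant" else raw$implant_id)
      p <- file.path(out_dir, "calibration.json")
      jsonlite::write_json(unclass(cal), p, auto_unbox = TRUE, digits = NA)
      list(calibration = cal, result = p)
    },
    "predict" = {
      cal <- .read_calibration(raw$calibration)
      dt <- predict_dt(cal, raw$i_mri)
      p <- file.path(out_dir, "prediction.json")
      jsonlite::write_json(list(i_mri_A = raw$i_mri, dt_K = dt),
                           p, auto_unbox = TRUE, digits = NA)
      list(dt = dt, result = p)
    },
    "limit" = {
      cal <- .read_calibration(raw$calibration)
      dt_thresh <- if (is.null(raw$dt_thresh)) 2 else raw$dt_thresh
      b1 <- b1_threshold(cal, raw$i_mri, config$seq_par$b1_rms_seq,
                         dt_thresh)
      p <- file.path(out_dir, "limit.json")
      jsonlite::write_json(list(i_mri_A = raw$i_mri,
                                dt_thresh_K = dt_thresh,
                                b1_rms_thresh_uT = b1),
                           p, auto_unbox = TRUE, digits = NA)
      list(b1_rms_thresh = b1, result = p)
    })
  invisible(res)
}

.read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  implant_calibration(x$c_implant, x$b1_rms_ref, x$slice_distance,
                      x$implant_id, x$r_squared)
}
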