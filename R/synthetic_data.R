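#' Synthetic scene specification
#'
#' Ground truth for a synthetic acquisition: the wire/background model
#' parameters, patch geometry, sequence parameters, the true T1 of the
#' medium, and the acquisition noise model. Noise is applied to the raw
#' magnitudes before per-voxel normalization, since normalization is a
#' processing step, not part of the acquisition.
#'
#' @param params a [wire_model_params()] ground truth.
#' @param geom a [patch_geometry()].
#' @param seq_par a [sequence_params()].
#' @param t1_true true longitudinal relaxation time, ms.
#' @param noise_sigma noise standard deviation relative to the mean raw
#'   noiseless signal over the patch. `NULL` (default) selects the level at
#'   which the strongest unperturbed background signal has SNR 20,
#'   emulating body-coil reception.
#' @param noise_model `"gaussian"` (noise added to magnitudes, clipped at
#'   zero by taking the magnitude) or `"rician"` (magnitude of a complex
#'   signal with independent Gaussian noise on both channels).
#' @param seed RNG seed recorded with every generated patch.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(params, geom = patch_geometry(),
                       seq_par = sequence_params(), t1_true = 1000,
                       noise_sigma = NULL,
                       noise_model = c("gaussian", "rician"), seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(inherits(params, "wire_model_params"), t1_true > 0,
            is.null(noise_sigma) || noise_sigma >= 0)
  structure(list(params = params, geom = geom, seq_par = seq_par,
                 t1_true = t1_true, noise_sigma = noise_sigma,
                 noise_model = noise_model, seed = as.integer(seed)),
            class = "scene_spec")
}

# Absolute noise SD for a scene: explicit relative sigma times the mean raw
# signal, or the auto rule (strongest background signal / 20).
.noise_sd_abs <- function(spec, dict, raw) {
  if (is.null(spec$noise_sigma)) {
    bg <- abs(.dict_interp(dict, spec$params$background$lambda_b))
    return(max(bg) / 20)
  }
  spec$noise_sigma * mean(abs(raw), na.rm = TRUE)
}

#' Generate a (possibly noisy) synthetic signal patch
#'
#' Synthesizes the noiseless raw signals of the scene with the forward
#' model, adds magnitude noise per the scene's noise model, then normalizes
#' per voxel and packages the result with its provenance and ground truth.
#' Deterministic for a given spec (the spec's seed drives all randomness).
#'
#' @param spec a [scene_spec()].
#' @param dict a slice dictionary matching the scene's sequence and T1.
#' @return A list: `patch` (a `signal_patch` with provenance
#'   `"synthetic"`), `truth` (the scene spec), `noise_sd` (absolute noise
#'   SD applied to the raw magnitudes).
#' @export
generate_patch <- function(spec, dict) {
  stopifnot(inherits(spec, "scene_spec"), inherits(dict, "slice_dictionary"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(spec$seed)
  fw <- .forward_raw(spec$params, spec$seq_par, dict, spec$geom)
  raw <- abs(fw$raw)
  sd_abs <- .noise_sd_abs(spec, dict, raw)
  if (sd_abs > 0) {
    n_val <- length(raw)
    noisy <- switch(spec$noise_model,
      gaussian = abs(raw + matrix(stats::rnorm(n_val, 0, sd_abs), nrow(raw))),
      rician = sqrt((raw + matrix(stats::rnorm(n_val, 0, sd_abs),
                                  nrow(raw)))^2 +
                    matrix(stats::rnorm(n_val, 0, sd_abs), nrow(raw))^2))
  } else {
    noisy <- raw
  }
  nrm <- sqrt(rowSums(noisy^2))
  degen <- fw$degenerate | (!is.na(nrm) & nrm == 0)
  norm <- noisy / nrm
  norm[degen, ] <- NA_real_
  patch <- .as_signal_patch(norm, degen, spec$geom, provenance = "synthetic",
                            seed = spec$seed)
  list(patch = patch, truth = spec, noise_sd = sd_abs)
}

#' Current profile along a wire
#'
#' Describes a current amplitude profile sampled at axial slice positions
#' along the wire, emulating a multi-slice validation design where the
#' current is measured in each slice of a stack.
#'
#' @param slice_positions positions along the wire, mm, strictly
#'   increasing.
#' @param profile current amplitude per slice, amperes.
#' @return An object of class `current_profile`.
#' @export
current_profile <- function(slice_positions, profile) {
  stopifnot(length(slice_positions) == length(profile), all(profile >= 0))
  if (is.unsorted(slice_positions, strictly = TRUE))
    stop("slice_positions must be strictly increasing")
  structure(list(slice_positions = slice_positions, profile = profile,
                 n_slices = length(profile)),
            class = "current_profile")
}

#' Scenes along a current profile
#'
#' One scene specification per slice of a current profile, sharing the base
#' scene's geometry, background and noise settings, with that slice's
#' current and a per-slice seed derived from the base seed.
#'
#' @param profile a [current_profile()].
#' @param base a [scene_spec()] providing everything except the current.
#' @return A list of `scene_spec`, one per slice.
#' @export
generate_profile_scenes <- function(profile, base) {
  stopifnot(inherits(profile, "current_profile"),
            inherits(base, "scene_spec"))
  lapply(seq_len(profile$n_slices), function(k) {
    p <- base$params
    p$i_rms <- profile$profile[k]
    scene_spec(p, base$geom, base$seq_par, base$t1_true, base$noise_sigma,
               base$noise_model, seed = base$seed + k)
  })
}

#' Generate a synthetic thermometry time series
#'
#' Emulates a fiber-optic probe recording at the implant tip: a flat
#' baseline followed by an exposure segment whose temperature rises
#' linearly to `c_implant * i^2` at the end of the exposure (short-time
#' heating in an inert phantom), plus an optional linear drift and
#' additive Gaussian noise.
#'
#' @param c_implant heating constant, K per ampere squared.
#' @param i wire current, amperes.
#' @param duration exposure duration, seconds (> 20).
#' @param baseline baseline duration before exposure, seconds.
#' @param drift linear temperature drift, K per second.
#' @param noise_sd probe noise SD, kelvin.
#' @param seed RNG seed.
#' @param sampling sampling interval, seconds.
#' @return A [thermo_series()].
#' @export
generate_thermometry <- function(c_implant, i, duration = 139,
                                 baseline = 300, drift = 0, noise_sd = 0,
                                 seed = 1L, sampling = 0.5) {
  stopifnot(duration > 20, baseline > 0, noise_sd >= 0, sampling > 0)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  time <- seq(0, baseline + duration, by = sampling)
  heat <- pmax(time - baseline, 0) / duration * c_implant * i^2
  temp <- heat + drift * time +
    if (noise_sd > 0) stats::rnorm(length(time), 0, noise_sd) else 0
  thermo_series(time, temp, exposure_start = baseline)
}
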