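#' da-hdrAFI acquisition parameters
#'
#' Parameters of the dual-angle high-dynamic-range actual flip-angle imaging
#' sequence: two interleaved gradient-echo acquisitions with different flip
#' angles and repetition times, acquired twice with different parameter sets
#' ((a) and (b)), yielding four magnitude images. Defaults are the nominal
#' protocol values used throughout this package.
#'
#' @param alpha_a1,alpha_a2,alpha_b1,alpha_b2 nominal flip angles, degrees,
#'   in (0, 180).
#' @param tr_a1,tr_a2,tr_b1,tr_b2 repetition times, ms, > 0.
#' @param b1_rms_seq nominal B1rms of the current-measurement sequence,
#'   microtesla. Fitted currents are referenced to this value.
#' @return An object of class `sequence_params`.
#' @export
sequence_params <- function(alpha_a1 = 45.2, alpha_a2 = 69.3,
                            tr_a1 = 23.7, tr_a2 = 61.5,
                            alpha_b1 = 21.9, alpha_b2 = 39.0,
                            tr_b1 = 26.5, tr_b2 = 188.5,
                            b1_rms_seq = 0.84) {
  angles <- c(alpha_a1, alpha_a2, alpha_b1, alpha_b2)
  trs <- c(tr_a1, tr_a2, tr_b1, tr_b2)
  stopifnot(all(angles > 0), all(angles < 180), all(trs > 0),
            b1_rms_seq > 0)
  structure(list(alpha_a1 = alpha_a1, alpha_a2 = alpha_a2,
                 tr_a1 = tr_a1, tr_a2 = tr_a2,
                 alpha_b1 = alpha_b1, alpha_b2 = alpha_b2,
                 tr_b1 = tr_b1, tr_b2 = tr_b2,
                 b1_rms_seq = b1_rms_seq),
            class = "sequence_params")
}

#' Steady-state signals of a dual-angle AFI acquisition
#'
#' Analytical steady-state signal pair of one dual-angle AFI sequence: two
#' interleaved spoiled gradient-echo excitations at nominal flip angles
#' `alpha1`, `alpha2` and repetition times `TR1`, `TR2`. With
#' `E_i = exp(-TR_i / T1)` and a local relative transmit field `lambda`,
#'
#'   S1 = (1 - E2 + (1 - E1) E2 cos(lambda a2)) /
#'        (1 - E1 E2 cos(lambda a1) cos(lambda a2)) * sin(lambda a1)
#'
#' and symmetrically for S2 (exchange indices 1 and 2). Both signals are zero
#' at `lambda = 0`, periodic in `lambda * alpha`, and reduce to
#' `sin(lambda alpha_i)` in the fully relaxed limit. Signed values are
#' returned: through-plane and sub-voxel averaging is coherent, so averaging
#' precedes taking the magnitude.
#'
#' @param lambda relative transmit field, dimensionless, >= 0; vectorized
#'   (vector or matrix).
#' @param t1 longitudinal relaxation time, ms.
#' @param seq_par a [sequence_params()].
#' @param which `"a"` or `"b"`, selecting the acquisition parameter set.
#' @return A list with elements `s1` and `s2`, shaped like `lambda`.
#' @export
afi_signals <- function(lambda, t1, seq_par, which = c("a", "b")) {
  which <- match.arg(which)
  stopifnot(t1 > 0)
  if (which == "a") {
    a1 <- seq_par$alpha_a1 * pi / 180; a2 <- seq_par$alpha_a2 * pi / 180
    e1 <- exp(-seq_par$tr_a1 / t1);    e2 <- exp(-seq_par$tr_a2 / t1)
  } else {
    a1 <- seq_par$alpha_b1 * pi / 180; a2 <- seq_par$alpha_b2 * pi / 180
    e1 <- exp(-seq_par$tr_b1 / t1);    e2 <- exp(-seq_par$tr_b2 / t1)
  }
  c1 <- cos(lambda * a1); c2 <- cos(lambda * a2)
  den <- 1 - e1 * e2 * c1 * c2
  list(s1 = (1 - e2 + (1 - e1) * e2 * c2) / den * sin(lambda * a1),
       s2 = (1 - e1 + (1 - e2) * e1 * c1) / den * sin(lambda * a2))
}

#' Slice-selective excitation pulse specification
#'
#' Describes the RF excitation pulse used for the Bloch-simulated
#' through-slice flip-angle profile. The default is a Hann-windowed sinc of
#' time-bandwidth product 4, a standard product-sequence excitation.
#'
#' @param shape `"hann_sinc"` or `"boxcar"` (the latter is an idealized
#'   rectangular profile, useful for degenerate-case checks).
#' @param tbw time-bandwidth product of the pulse.
#' @param n_samples number of hard-pulse samples in the Bloch simulation.
#' @param ref_flip_deg small reference flip angle (degrees) at which the
#'   profile is simulated; the profile is then scaled linearly to the
#'   nominal flip angles.
#' @return An object of class `pulse_spec`.
#' @export
pulse_spec <- function(shape = c("hann_sinc", "boxcar"), tbw = 4,
                       n_samples = 200L, ref_flip_deg = 10) {
  shape <- match.arg(shape)
  stopifnot(tbw > 0, n_samples >= 8, ref_flip_deg > 0, ref_flip_deg < 30)
  structure(list(shape = shape, tbw = tbw, n_samples = as.integer(n_samples),
                 ref_flip_deg = ref_flip_deg),
            class = "pulse_spec")
}

# Through-slice flip-angle profile p(z) from a hard-pulse Bloch simulation.
# z in units of the slice thickness, profile normalized to 1 at slice center.
# Relaxation during the (short) pulse is neglected; the refocusing gradient
# affects transverse phase only, which does not enter the flip magnitude.
.bloch_flip_profile <- function(pulse, z_rel) {
  if (pulse$shape == "boxcar")
    return(as.numeric(abs(z_rel) <= 0.5))
  n <- pulse$n_samples
  tt <- seq(-0.5, 0.5, length.out = n)        # normalized pulse time
  env <- switch(pulse$shape,
                hann_sinc = {
                  x <- pulse$tbw * tt
                  (0.5 + 0.5 * cos(2 * pi * tt)) * ifelse(x == 0, 1, sin(pi * x) / (pi * x))
                })
  flip_ref <- pulse$ref_flip_deg * pi / 180
  theta <- env / sum(env) * flip_ref           # per-sample tip about x
  # off-resonance per sample: slice-select gradient maps z (in slice
  # thicknesses) to frequency offset z * BW, BW = tbw / duration
  dphi <- 2 * pi * pulse$tbw * z_rel / n
  nz <- length(z_rel)
  mx <- numeric(nz); my <- numeric(nz); mz <- rep(1, nz)
  for (k in seq_len(n)) {
    ct <- cos(theta[k]); st <- sin(theta[k])
    my2 <- ct * my - st * mz
    mz2 <- st * my + ct * mz
    my <- my2; mz <- mz2
    cp <- cos(dphi); sp <- sin(dphi)
    mx2 <- cp * mx - sp * my
    my <- sp * mx + cp * my
    mx <- mx2
  }
  flip <- acos(pmin(pmax(mz, -1), 1))
  flip_center <- flip[which.min(abs(z_rel))]
  if (flip_center <= 0) stop("degenerate pulse: zero on-slice flip")
  flip / flip_center
}

#' Build the slice-profile signal dictionary
#'
#' Precomputes the through-plane-averaged da-hdrAFI signals as a function of
#' the relative transmit field at the center of the slice. For each `lambda`
#' on the grid, the local effective excitation at through-plane position `z`
#' is `alpha * lambda * p(z)`, with `p(z)` the Bloch-simulated flip-angle
#' profile of the excitation pulse; the four steady-state signals are
#' averaged over the through-plane positions. The dictionary replaces
#' per-voxel Bloch simulation during fitting.
#'
#' @param seq_par a [sequence_params()].
#' @param pulse a [pulse_spec()].
#' @param t1 longitudinal relaxation time of the medium, ms.
#' @param lambda_grid ascending grid of center-of-slice relative field
#'   values. The default (0 to 30 in steps of 0.01) covers the near-wire
#'   hotspot's dynamic range at phantom-regime currents.
#' @param n_positions number of through-plane positions averaged (default
#'   201).
#' @param z_extent half-extent of the through-plane averaging window in
#'   units of the slice thickness (default 2, capturing transition bands).
#' @return An object of class `slice_dictionary`: the grid, an
#'   `n_lambda x 4` signal matrix (columns `s_a1, s_a2, s_b1, s_b2`, signed
#'   through-plane averages) and the profile metadata.
#' @export
build_slice_dictionary <- function(seq_par, pulse = pulse_spec(), t1 = 1000,
                                   lambda_grid = seq(0, 30, by = 0.01),
                                   n_positions = 201L, z_extent = 2) {
  stopifnot(inherits(seq_par, "sequence_params"), inherits(pulse, "pulse_spec"),
            t1 > 0, n_positions >= 3, z_extent > 0)
  if (is.unsorted(lambda_grid, strictly = TRUE))
    stop("lambda_grid must be strictly ascending")
  if (lambda_grid[1] < 0) stop("lambda_grid must be nonnegative")
  z_rel <- seq(-z_extent, z_extent, length.out = n_positions)
  prof <- .bloch_flip_profile(pulse, z_rel)
  lam_eff <- outer(lambda_grid, prof)          # n_lambda x n_positions
  sig_a <- afi_signals(lam_eff, t1, seq_par, "a")
  sig_b <- afi_signals(lam_eff, t1, seq_par, "b")
  signals <- cbind(s_a1 = rowMeans(sig_a$s1), s_a2 = rowMeans(sig_a$s2),
                   s_b1 = rowMeans(sig_b$s1), s_b2 = rowMeans(sig_b$s2))
  step <- diff(lambda_grid)
  uniform <- max(step) - min(step) < 1e-9 * mean(step)
  structure(list(lambda_grid = lambda_grid, signals = signals,
                 uniform_step = if (uniform) mean(step) else NA_real_,
                 profile_meta = list(pulse = pulse, t1 = t1,
                                     n_positions = as.integer(n_positions),
                                     z_extent = z_extent,
                                     profile = prof, z_rel = z_rel),
                 seq_par = seq_par),
            class = "slice_dictionary")
}

# Vectorized interpolation without range checks beyond NA flagging.
# Returns an n x 4 matrix; rows with lambda outside the grid are NA.
.dict_interp <- function(dict, lambda) {
  grid <- dict$lambda_grid
  n <- length(grid)
  out_of_range <- lambda < grid[1] | lambda > grid[n] | !is.finite(lambda)
  lam <- ifelse(out_of_range, grid[1], lambda)
  if (!is.na(dict$uniform_step)) {
    pos <- (lam - grid[1]) / dict$uniform_step
    i0 <- pmin(floor(pos), n - 2) + 1
    frac <- pos - (i0 - 1)
  } else {
    i0 <- pmin(findInterval(lam, grid), n - 1)
    frac <- (lam - grid[i0]) / (grid[i0 + 1] - grid[i0])
  }
  s <- dict$signals
  out <- s[i0, , drop = FALSE] * (1 - frac) + s[i0 + 1, , drop = FALSE] * frac
  out[out_of_range, ] <- NA_real_
  out
}

#' Look up dictionary signals at given relative field values
#'
#' Linear interpolation of the four through-plane-averaged signals between
#' neighboring dictionary rows; exact at grid nodes. Values outside the grid
#' range are an error (the dictionary is never extrapolated).
#'
#' @param dict a [build_slice_dictionary()] result.
#' @param lambda relative field value(s) within the grid range.
#' @return A numeric matrix, one row per `lambda`, columns
#'   `s_a1, s_a2, s_b1, s_b2`.
#' @export
lookup_signals <- function(dict, lambda) {
  stopifnot(inherits(dict, "slice_dictionary"))
  grid <- dict$lambda_grid
  if (any(!is.finite(lambda)) || any(lambda < grid[1]) ||
      any(lambda > grid[length(grid)]))
    stop("lambda outside the dictionary grid range [",
         grid[1], ", ", grid[length(grid)], "]")
  .dict_interp(dict, lambda)
}

#' Normalize the four signals of a voxel
#'
#' Divides each of the four da-hdrAFI magnitude signals of a voxel by the
#' Euclidean norm of the four, yielding a unit-norm signal vector. The
#' normalization is invariant under any common positive scaling of the
#' inputs, which removes receive-field amplitude, proton density and T2*
#' weighting from the data.
#'
#' @param signals numeric vector of 4 nonnegative magnitudes, or a matrix
#'   with 4 columns (one voxel per row).
#' @return Normalized signals, same shape as the input.
#' @export
normalize_voxel <- function(signals) {
  if (is.matrix(signals)) {
    stopifnot(ncol(signals) == 4)
    nrm <- sqrt(rowSums(signals^2))
    if (any(nrm == 0)) stop("degenerate voxel: all four signals are zero")
    return(signals / nrm)
  }
  stopifnot(length(signals) == 4)
  nrm <- sqrt(sum(signals^2))
  if (nrm == 0) stop("degenerate voxel: all four signals are zero")
  signals / nrm
}

#' Serialize a slice dictionary to a text file
#'
#' Writes the dictionary as CSV with a commented metadata header, so it can
#' be rebuilt or inspected without re-running the Bloch simulation.
#'
#' @param dict a `slice_dictionary`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dictionary <- function(dict, path) {
  stopifnot(inherits(dict, "slice_dictionary"))
  meta <- dict$profile_meta
  hdr <- c(
    sprintf("# pulse_shape=%s", meta$pulse$shape),
    sprintf("# pulse_tbw=%g", meta$pulse$tbw),
    sprintf("# pulse_n_samples=%d", meta$pulse$n_samples),
    sprintf("# pulse_ref_flip_deg=%g", meta$pulse$ref_flip_deg),
    sprintf("# t1_ms=%g", meta$t1),
    sprintf("# n_positions=%d", meta$n_positions),
    sprintf("# z_extent=%g", meta$z_extent),
    sprintf("# seq=%s", paste(unlist(dict$seq_par), collapse = ","))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(data.frame(lambda = dict$lambda_grid, dict$signals),
                   con, row.names = FALSE)
  invisible(path)
}

#' Read a serialized slice dictionary
#'
#' @param path file written by [write_dictionary()].
#' @return A `slice_dictionary` (profile vector omitted; signals and grid as
#'   written).
#' @export
read_dictionary <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- do.call(rbind, strsplit(sub("^# ", "", hdr), "="))
  meta <- stats::setNames(as.list(kv[, 2]), kv[, 1])
  tab <- utils::read.csv(text = lines[!grepl("^#", lines)])
  seqv <- as.numeric(strsplit(meta$seq, ",")[[1]])
  sq <- sequence_params(seqv[1], seqv[2], seqv[3], seqv[4],
                        seqv[5], seqv[6], seqv[7], seqv[8], seqv[9])
  grid <- tab$lambda
  step <- diff(grid)
  uniform <- max(step) - min(step) < 1e-9 * mean(step)
  structure(list(lambda_grid = grid,
                 signals = as.matrix(tab[, c("s_a1", "s_a2", "s_b1", "s_b2")]),
                 uniform_step = if (uniform) mean(step) else NA_real_,
                 profile_meta = list(
                   pulse = pulse_spec(meta$pulse_shape,
                                      as.numeric(meta$pulse_tbw),
                                      as.integer(meta$pulse_n_samples),
                                      as.numeric(meta$pulse_ref_flip_deg)),
                   t1 = as.numeric(meta$t1_ms),
                   n_positions = as.integer(meta$n_positions),
                   z_extent = as.numeric(meta$z_extent)),
                 seq_par = sq),
            class = "slice_dictionary")
}
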