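#' Thermometry time series
#'
#' A uniformly sampled temperature recording from a fiber-optic probe at the
#' implant tip, covering a pre-exposure baseline followed by the RF
#' exposure.
#'
#' @param time sample times, seconds, uniformly spaced ascending.
#' @param temperature temperatures, kelvin (or degrees Celsius; only
#'   differences are used).
#' @param exposure_start time at which RF exposure begins, seconds; the
#'   baseline is everything before it.
#' @return An object of class `thermo_series`.
#' @export
thermo_series <- function(time, temperature, exposure_start) {
  stopifnot(length(time) == length(temperature), length(time) >= 3,
            !is.unsorted(time, strictly = TRUE), is.finite(exposure_start))
  dt <- diff(time)
  if (max(dt) - min(dt) > 1e-6 * mean(dt))
    stop("sampling must be uniform")
  if (exposure_start <= time[1])
    stop("series contains no baseline before exposure_start")
  structure(list(time = time, temperature = temperature,
                 exposure_start = exposure_start),
            class = "thermo_series")
}

#' Scaled peak temperature rise from thermometry
#'
#' Baseline-corrects a probe recording and scales it against a reference
#' recording (the configuration with strongest heating): both series are
#' baseline-corrected by fitting a linear trend to the pre-exposure
#' baseline and subtracting its extrapolation (removing offset and slow
#' probe drift), the relative heating scale is the least-squares scalar
#' between the two corrected curves over the first `window` seconds of
#' exposure, and the scaled peak temperature rise is that scale applied to
#' the reference's peak. Scaling on the early heating segment, where
#' conduction losses are negligible, is more robust than comparing raw
#' peaks.
#'
#' @param series a [thermo_series()] for the configuration of interest.
#' @param reference a [thermo_series()] for the reference (strongest
#'   heating) configuration.
#' @param window scaling window after exposure start, seconds (default 20).
#' @return A list: `scale` (relative heating vs. the reference), `dt_peak`
#'   (scaled peak temperature increase, K), and `peak_reference` (the
#'   reference's own baseline-corrected peak, K).
#' @export
process_thermometry <- function(series, reference, window = 20) {
  stopifnot(inherits(series, "thermo_series"),
            inherits(reference, "thermo_series"))
  corr <- function(s) {
    sel <- s$time < s$exposure_start
    if (sum(sel) < 2) stop("missing baseline")
    if (max(s$time) < s$exposure_start + window)
      stop("exposure shorter than the scaling window")
    # remove the baseline's linear trend (probe offset and slow drift)
    tb <- s$time[sel]; yb <- s$temperature[sel]
    slope <- stats::cov(tb, yb) / stats::var(tb)
    icept <- mean(yb) - slope * mean(tb)
    list(y = s$temperature - (icept + slope * s$time),
         t = s$time - s$exposure_start)
  }
  a <- corr(series); b <- corr(reference)
  wa <- a$y[a$t >= 0 & a$t <= window]
  wb <- b$y[b$t >= 0 & b$t <= window]
  m <- min(length(wa), length(wb))
  wa <- wa[seq_len(m)]; wb <- wb[seq_len(m)]
  if (sum(wb^2) == 0) stop("reference series is flat over the scaling window")
  scale <- sum(wa * wb) / sum(wb^2)
  peak_ref <- max(b$y[b$t >= 0])
  list(scale = scale, dt_peak = scale * peak_ref, peak_reference = peak_ref)
}

#' Implant heating calibration
#'
#' The implant-specific proportionality constant `c_implant` linking the
#' squared RMS wire current to the temperature rise at a fixed probe point,
#' `dT = c_implant * I^2`. The constant is only meaningful at its stated
#' slice-to-tip distance and current reference B1rms.
#'
#' @param c_implant kelvin per ampere squared, >= 0.
#' @param b1_rms_ref B1rms (microtesla) to which calibrated currents are
#'   referenced.
#' @param slice_distance distance between the MRI acquisition slice and the
#'   implant tip, mm.
#' @param implant_id label.
#' @param r_squared coefficient of determination of the proportional fit,
#'   if fitted.
#' @return An object of class `implant_calibration`.
#' @export
implant_calibration <- function(c_implant, b1_rms_ref = NA_real_,
                                slice_distance = NA_real_,
                                implant_id = "implant",
                                r_squared = NA_real_) {
  stopifnot(is.finite(c_implant), c_implant >= 0)
  structure(list(c_implant = c_implant, b1_rms_ref = b1_rms_ref,
                 slice_distance = slice_distance, implant_id = implant_id,
                 r_squared = r_squared),
            class = "implant_calibration")
}

#' Re-reference a wire current to a different B1rms
#'
#' A wire current is induced by, and linearly related to, the background
#' field; a current reported at one B1rms converts to another by the ratio
#' of the fields.
#'
#' @param i_rms current, amperes.
#' @param from_b1,to_b1 B1rms values, microtesla.
#' @return Current referenced to `to_b1`, amperes.
#' @export
reference_current <- function(i_rms, from_b1, to_b1) {
  stopifnot(from_b1 > 0, to_b1 > 0)
  i_rms * to_b1 / from_b1
}

#' Calibrate the current-to-heating constant
#'
#' Least-squares proportional fit (no intercept) of observed temperature
#' rises against squared fitted currents across implant configurations:
#' `c = sum(dT_i I_i^2) / sum(I_i^4)`. All currents must be referenced to a
#' common B1rms before fitting.
#'
#' @param observations a data frame with columns `i_mri` (fitted current,
#'   A) and `dt_thermo` (scaled peak temperature rise, K); optional
#'   `config_label`.
#' @param b1_rms_ref,slice_distance,implant_id recorded in the calibration.
#' @return An [implant_calibration()] including the R-squared of the
#'   proportional model.
#' @export
fit_cimplant <- function(observations, b1_rms_ref = NA_real_,
                         slice_distance = NA_real_, implant_id = "implant") {
  stopifnot(is.data.frame(observations),
            all(c("i_mri", "dt_thermo") %in% names(observations)))
  i <- observations$i_mri
  dt <- observations$dt_thermo
  stopifnot(all(is.finite(i)), all(is.finite(dt)), all(i >= 0))
  if (all(i == 0)) stop("all currents are zero: c_implant undetermined")
  cc <- sum(dt * i^2) / sum(i^4)
  ss_res <- sum((dt - cc * i^2)^2)
  ss_tot <- sum((dt - mean(dt))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  implant_calibration(cc, b1_rms_ref, slice_distance, implant_id, r2)
}

#' Predict the temperature rise for a measured current
#'
#' Quadratic heating law: `dT = c_implant * I^2`, valid at the
#' calibration's probe point, slice distance and current reference.
#'
#' @param cal an [implant_calibration()].
#' @param i_mri fitted RMS current, amperes, referenced to
#'   `cal$b1_rms_ref`.
#' @return Predicted temperature rise, kelvin.
#' @export
predict_dt <- function(cal, i_mri) {
  stopifnot(inherits(cal, "implant_calibration"), all(i_mri >= 0))
  cal$c_implant * i_mri^2
}

#' Maximum allowable B1rms for a target temperature rise
#'
#' Given the current measured during a sequence with nominal B1rms
#' `b1_rms_seq`, the induced current at any other exposure scales with the
#' B1rms ratio, so the exposure limit that keeps heating at `dt_thresh` is
#'
#'   B1rms_thresh = b1_rms_seq * sqrt(dt_thresh / (c_implant * I^2)).
#'
#' The loop closes exactly: predicting heating at the current rescaled by
#' `B1rms_thresh / b1_rms_seq` returns `dt_thresh`.
#'
#' @param cal an [implant_calibration()].
#' @param i_mri fitted RMS current, amperes. A zero current implies no
#'   measured limit and returns `Inf`.
#' @param b1_rms_seq B1rms of the current-measurement sequence, microtesla.
#' @param dt_thresh threshold temperature increase, kelvin (default 2).
#' @return Maximum allowable nominal B1rms, microtesla.
#' @export
b1_threshold <- function(cal, i_mri, b1_rms_seq, dt_thresh = 2) {
  stopifnot(inherits(cal, "implant_calibration"), b1_rms_seq > 0)
  if (dt_thresh <= 0) stop("dt_thresh must be positive")
  pred <- cal$c_implant * i_mri^2
  if (pred == 0) return(Inf)
  b1_rms_seq * sqrt(dt_thresh / pred)
}

#' Leave-one-out evaluation of the calibration
#'
#' For each (current, temperature-rise) pair, `c_implant` is fitted from
#' the remaining pairs and used to convert between current and heating,
#' giving per-observation errors free of self-calibration bias: the
#' current error `|I_mri - I_thermo|` with `I_thermo = sqrt(dT / c)`, and
#' the heating error `|c * I_mri^2 - dT|`.
#'
#' @param observations as in [fit_cimplant()]; at least 3 rows.
#' @return A list with `per_observation` (data frame of held-out errors)
#'   and `summary` (medians and ranges of both error types).
#' @export
loo_evaluate <- function(observations) {
  stopifnot(is.data.frame(observations), nrow(observations) >= 3)
  n <- nrow(observations)
  err_i <- numeric(n); err_dt <- numeric(n); c_loo <- numeric(n)
  for (k in seq_len(n)) {
    cal <- fit_cimplant(observations[-k, , drop = FALSE])
    c_loo[k] <- cal$c_implant
    i_k <- observations$i_mri[k]
    dt_k <- observations$dt_thermo[k]
    i_thermo <- sqrt(max(dt_k, 0) / cal$c_implant)
    err_i[k] <- abs(i_k - i_thermo)
    err_dt[k] <- abs(cal$c_implant * i_k^2 - dt_k)
  }
  per <- data.frame(i_mri = observations$i_mri,
                    dt_thermo = observations$dt_thermo,
                    c_loo = c_loo, err_current = err_i, err_dt = err_dt)
  list(per_observation = per,
       summary = list(
         median_err_current = stats::median(err_i),
         range_err_current = range(err_i),
         median_err_dt = stats::median(err_dt),
         range_err_dt = range(err_dt)))
}
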