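# Optical signal chain: raw detector units <-> percent transmittance <->
# absorbance, forward models for the two readouts (cell turbidity, phenol-red
# pH), and the acquisition chain (sampling + boxcar averaging + noise).

#' Detector calibration record
#'
#' A two-point calibration defining relative transmittance at 560 nm: the dark
#' signal (total obscurity, 0\% T) and the blank signal (cell-free reference
#' liquid, 100\% T).
#'
#' @param dark_signal Raw detector reading under total obscurity (defines 0\% T).
#' @param blank_signal Raw detector reading through the blank (defines 100\% T);
#'   must exceed `dark_signal`.
#' @param wavelength Wavelength in nm; fixed at 560 and carried as metadata.
#' @param label Free-text label (e.g. the blank liquid used).
#' @return An object of class `calibration_record`.
#' @examples
#' cal <- calibration_record(dark_signal = 0.05, blank_signal = 4.05)
#' raw_to_transmittance(2.05, cal)
#' @export
calibration_record <- function(dark_signal, blank_signal, wavelength = 560,
                               label = "") {
  stopifnot(is.numeric(dark_signal), is.numeric(blank_signal),
            length(dark_signal) == 1L, length(blank_signal) == 1L)
  if (!isTRUE(blank_signal > dark_signal)) {
    stop("invalid calibration: blank_signal must exceed dark_signal",
         call. = FALSE)
  }
  if (!identical(as.numeric(wavelength), 560)) {
    stop("wavelength is fixed at 560 nm in this hardware revision",
         call. = FALSE)
  }
  structure(list(dark_signal = as.numeric(dark_signal),
                 blank_signal = as.numeric(blank_signal),
                 wavelength = 560, label = label),
            class = "calibration_record")
}

#' Acquisition settings
#'
#' @param sample_period Seconds between detector samples (> 0).
#' @param n_average Boxcar window length in samples (integer >= 1).
#' @param noise_sd Standard deviation of additive Gaussian detector noise, in
#'   raw-signal units (0 = noise-free).
#' @param rng_seed Optional integer seed recorded with the run.
#' @return An object of class `acquisition_settings`.
#' @export
acquisition_settings <- function(sample_period = 1, n_average = 1,
                                 noise_sd = 0, rng_seed = NULL) {
  stopifnot(sample_period > 0, noise_sd >= 0)
  n_average <- as.integer(n_average)
  if (is.na(n_average) || n_average < 1L) {
    stop("n_average must be an integer >= 1", call. = FALSE)
  }
  structure(list(sample_period = as.numeric(sample_period),
                 n_average = n_average, noise_sd = as.numeric(noise_sd),
                 rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed)),
            class = "acquisition_settings")
}

#' Optical model parameters
#'
#' Parameters of the two forward models feeding the detector: turbidity
#' (absorbance linear in cell density, Beer-Lambert) and the phenol-red pH
#' response (piecewise linear in pH, saturating outside the indicator window).
#'
#' @param k_cell Absorbance units per (CFU/mL) per cm of optical path; 0 for
#'   cells too small to scatter light.
#' @param path_length Optical path length in cm.
#' @param phenolred_A_min Medium absorbance at or below `pH_lo`.
#' @param phenolred_A_max Medium absorbance at or above `pH_hi`.
#' @param pH_lo,pH_hi Bounds of the linear indicator window (default 6 and 7,
#'   the range over which the 560 nm response is linear in pH).
#' @return An object of class `optical_model_params`.
#' @export
optical_model_params <- function(k_cell, path_length = 1,
                                 phenolred_A_min = 0, phenolred_A_max = 0,
                                 pH_lo = 6, pH_hi = 7) {
  stopifnot(k_cell >= 0, path_length > 0,
            phenolred_A_min >= 0, phenolred_A_max >= phenolred_A_min,
            pH_hi > pH_lo)
  structure(list(k_cell = as.numeric(k_cell),
                 path_length = as.numeric(path_length),
                 phenolred_A_min = as.numeric(phenolred_A_min),
                 phenolred_A_max = as.numeric(phenolred_A_max),
                 pH_lo = as.numeric(pH_lo), pH_hi = as.numeric(pH_hi)),
            class = "optical_model_params")
}

#' Ordered signal trace
#'
#' @param time Strictly increasing times, seconds.
#' @param value Signal values (raw units or percent).
#' @return A data frame of class `signal_trace` with columns `time`, `value`.
#' @export
signal_trace <- function(time, value) {
  stopifnot(length(time) == length(value))
  if (length(time) > 1L && any(diff(time) <= 0)) {
    stop("trace times must be strictly increasing", call. = FALSE)
  }
  structure(data.frame(time = as.numeric(time), value = as.numeric(value)),
            class = c("signal_trace", "data.frame"))
}

#' Convert a raw detector reading to percent transmittance
#'
#' Affine map through the two calibration points: 100 * (raw - dark) /
#' (blank - dark). Values below 0\% or above 100\% are returned unmodified and
#' flagged in the `out_of_range` attribute rather than clipped, so that
#' calibration drift stays visible.
#'
#' @param raw Raw detector reading(s).
#' @param calib A [calibration_record()].
#' @return Numeric vector of percent transmittance with a logical attribute
#'   `out_of_range`.
#' @export
raw_to_transmittance <- function(raw, calib) {
  stopifnot(inherits(calib, "calibration_record"))
  T_pct <- 100 * (raw - calib$dark_signal) /
    (calib$blank_signal - calib$dark_signal)
  structure(T_pct, out_of_range = T_pct < 0 | T_pct > 100)
}

#' Absorbance from percent transmittance
#'
#' A = -log10(T / 100); additive across independent absorbers (Beer-Lambert).
#'
#' @param T_pct Percent transmittance, must be > 0.
#' @return Absorbance units.
#' @export
absorbance_from_transmittance <- function(T_pct) {
  if (any(!is.finite(T_pct)) || any(T_pct <= 0)) {
    stop("transmittance must be finite and > 0 to take an absorbance",
         call. = FALSE)
  }
  -log10(T_pct / 100)
}

#' Turbidity forward model: absorbance of the cell suspension
#'
#' Beer-Lambert: A = k_cell * X * path_length, linear in cell density.
#'
#' @param X Cell density, CFU/mL (>= 0).
#' @param params An [optical_model_params()].
#' @return Absorbance units.
#' @export
cell_absorbance <- function(X, params) {
  stopifnot(inherits(params, "optical_model_params"))
  if (any(X < 0)) stop("cell density must be >= 0", call. = FALSE)
  params$k_cell * X * params$path_length
}

#' Phenol-red forward model: medium absorbance as a function of pH
#'
#' Piecewise linear with saturation: A_min at or below `pH_lo`, A_max at or
#' above `pH_hi`, linear interpolation between. Monotone non-decreasing in pH;
#' as the medium acidifies, 560 nm absorbance drops and transmittance rises.
#'
#' @param pH pH value(s).
#' @param params An [optical_model_params()].
#' @return Absorbance units.
#' @export
phenolred_absorbance <- function(pH, params) {
  stopifnot(inherits(params, "optical_model_params"))
  frac <- pmin(1, pmax(0, (pH - params$pH_lo) / (params$pH_hi - params$pH_lo)))
  params$phenolred_A_min +
    frac * (params$phenolred_A_max - params$phenolred_A_min)
}

#' Percent transmittance from component absorbances
#'
#' Closure of the Beer-Lambert additivity: T = 100 * 10^-(A_cells + A_medium).
#'
#' @param A_cells Cell-suspension absorbance (>= 0).
#' @param A_medium Medium absorbance relative to the blank (>= 0).
#' @return Percent transmittance.
#' @export
transmittance_from_components <- function(A_cells, A_medium) {
  if (any(A_cells < 0) || any(A_medium < 0)) {
    stop("component absorbances must be >= 0", call. = FALSE)
  }
  100 * 10^(-(A_cells + A_medium))
}

#' Trailing boxcar (moving-average) filter
#'
#' Each output value is the mean of the last `min(k, n_average)` samples at
#' position k; output times equal input times. With `n_average = 1` the trace
#' is returned unchanged.
#'
#' @param trace A [signal_trace()] or a bare numeric vector.
#' @param n_average Window length in samples (integer >= 1).
#' @return Same shape as `trace`, filtered.
#' @export
boxcar_filter <- function(trace, n_average) {
  n_average <- as.integer(n_average)
  if (is.na(n_average) || n_average < 1L) {
    stop("n_average must be an integer >= 1", call. = FALSE)
  }
  v <- if (inherits(trace, "signal_trace")) trace$value else as.numeric(trace)
  m <- length(v)
  if (m == 0L) return(trace)
  cs <- cumsum(v)
  k <- seq_len(m)
  lead <- pmin(k, n_average)
  idx <- k - n_average
  prev <- numeric(m)
  prev[idx >= 1L] <- cs[idx[idx >= 1L]]
  out <- (cs - prev) / lead
  if (inherits(trace, "signal_trace")) {
    trace$value <- out
    trace
  } else {
    out
  }
}

#' Simulate one detector reading
#'
#' Maps a true percent transmittance back onto the raw-signal scale defined by
#' the calibration and adds Gaussian noise with sd `acq$noise_sd` in raw-signal
#' space (where a real photoreceiver's noise lives). With `noise_sd = 0` the
#' reading round-trips exactly through [raw_to_transmittance()]. Draws from
#' R's global RNG; seed via `set.seed()` for reproducibility.
#'
#' @param true_T True percent transmittance.
#' @param calib A [calibration_record()].
#' @param acq An [acquisition_settings()].
#' @return Raw detector units.
#' @export
sample_measurement <- function(true_T, calib, acq) {
  stopifnot(inherits(calib, "calibration_record"),
            inherits(acq, "acquisition_settings"))
  raw <- calib$dark_signal +
    true_T / 100 * (calib$blank_signal - calib$dark_signal)
  if (acq$noise_sd > 0) {
    raw <- raw + stats::rnorm(length(raw), 0, acq$noise_sd)
  }
  raw
}
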