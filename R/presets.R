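# Named preset bundles reproducing the three study scenarios: a turbidity-
# monitored E. coli-like culture, a phenol-red-monitored M. florum-like
# culture (cells too small to scatter light), and a slower turbidity-
# monitored yeast-like culture. Kinetic and optical parameter values are
# fixture choices calibrated to the qualitative behavior of each scenario,
# not measured constants; the continuous-culture mode settings are the
# operating setpoints of the corresponding experiments.

.presets <- function() {
  list(
    "ecoli-like" = function(duration, seed) {
      # ~25 doublings / 12 h at full rate; T = 25% at 1e8 CFU/mL
      opt <- optical_model_params(k_cell = 6e-9, path_length = 1)
      org <- organism_params(mu_max = log(2) / 0.48, Ks = 0.05,
                             yield_Y = 5e8, q_acid = 0, optics = opt)
      experiment_config(
        duration = duration,
        acquisition = acquisition_settings(sample_period = 5, n_average = 1,
                                           noise_sd = 0, rng_seed = seed),
        mode = mode_threshold_activated(trigger_T = 50, pinch_time = 3,
                                        n_cycles = 1),
        polarity = "growth_decreases_T",
        organism = org,
        medium = medium_spec(S0 = 5, pH0 = 7, buffer_capacity = 1,
                             phenol_red = FALSE),
        calibration = calibration_record(0.05, 4.05, label = "broth blank"),
        inoculum = list(X = 5e6),
        seed = seed)
    },
    "mflorum-like" = function(duration, seed) {
      # turbidity-silent cells; growth read through medium acidification:
      # fresh medium T = 8%, fully acidified T = 16%, linear over pH 6-7
      opt <- optical_model_params(k_cell = 0, path_length = 1,
                                  phenolred_A_min = -log10(0.16),
                                  phenolred_A_max = -log10(0.08),
                                  pH_lo = 6, pH_hi = 7)
      org <- organism_params(mu_max = log(2) / 0.6, Ks = 0.02,
                             yield_Y = 5e9, q_acid = 1e-10, optics = opt)
      experiment_config(
        duration = duration,
        acquisition = acquisition_settings(sample_period = 0.5, n_average = 2,
                                           noise_sd = 0, rng_seed = seed),
        mode = mode_realtime_feedback(trigger_T = 12, release_T = 11.5,
                                      max_cycle_pinch_time = 10),
        polarity = "growth_increases_T",
        organism = org,
        medium = medium_spec(S0 = 5, pH0 = 7, buffer_capacity = 1,
                             phenol_red = TRUE),
        calibration = calibration_record(0.05, 4.05, label = "water blank"),
        inoculum = list(X = 5e8),
        seed = seed)
    },
    "yeast-like" = function(duration, seed) {
      opt <- optical_model_params(k_cell = 3e-8, path_length = 1)
      org <- organism_params(mu_max = log(2) / 1.5, Ks = 0.05,
                             yield_Y = 2e8, q_acid = 0, optics = opt)
      experiment_config(
        duration = duration,
        acquisition = acquisition_settings(sample_period = 5, n_average = 1,
                                           noise_sd = 0, rng_seed = seed),
        mode = mode_threshold_activated(trigger_T = 50, pinch_time = 3,
                                        n_cycles = 1),
        polarity = "growth_decreases_T",
        organism = org,
        medium = medium_spec(S0 = 20, pH0 = 7, buffer_capacity = 1,
                             phenol_red = FALSE),
        calibration = calibration_record(0.05, 4.05, label = "medium blank"),
        inoculum = list(X = 1e6),
        seed = seed)
    })
}

#' Preset experiment configurations
#'
#' Ready-to-run [experiment_config()] bundles for the three reference
#' scenarios. `"ecoli-like"` and `"yeast-like"` are turbidity-monitored
#' cultures run in the threshold-activated mode (minimum transmittance 50\%,
#' one 3 s cycle); `"mflorum-like"` is a phenol-red-monitored culture run in
#' the real-time feedback mode (thresholds 12\% / 11.5\%). Vessel (55 mL
#' capacity, 20 mL working volume) and flow (1 mL/s) use their defaults.
#'
#' @param name Preset name; see `preset_names()`.
#' @param duration Run length in hours.
#' @param seed Optional integer seed for detector noise.
#' @param mode Optional [mode_config] overriding the preset's operating mode.
#' @param acquisition Optional [acquisition_settings()] override.
#' @return An [experiment_config()].
#' @examples
#' cfg <- preset_config("ecoli-like", duration = 2)
#' @export
preset_config <- function(name, duration = 12, seed = NULL, mode = NULL,
                          acquisition = NULL) {
  ps <- .presets()
  if (!name %in% names(ps)) {
    stop(sprintf("unknown preset '%s'; available: %s", name,
                 paste(names(ps), collapse = ", ")), call. = FALSE)
  }
  cfg <- ps[[name]](duration, seed)
  if (!is.null(mode) || !is.null(acquisition)) {
    cfg <- experiment_config(
      duration = cfg$duration,
      acquisition = if (is.null(acquisition)) cfg$acquisition else acquisition,
      mode = if (is.null(mode)) cfg$mode else mode,
      polarity = cfg$polarity, organism = cfg$organism, medium = cfg$medium,
      calibration = cfg$calibration, vessel = cfg$vessel, flow = cfg$flow,
      inoculum = cfg$inoculum, channel_id = cfg$channel_id, seed = cfg$seed,
      valve_resolution = cfg$valve_resolution, cycle_cap = cfg$cycle_cap)
  }
  cfg
}

#' @rdname preset_config
#' @export
preset_names <- function() names(.presets())
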