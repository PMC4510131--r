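# Operating modes and the trigger decision logic: batch monitoring, real-time
# feedback turbidostat, threshold-activated turbidostat, and time-interval
# chemostat, for up to three independent channels.

#' Signal polarity of growth
#'
#' `"growth_decreases_T"`: turbidity readout — growing cells block light and
#' transmittance falls. `"growth_increases_T"`: phenol-red readout — growth
#' acidifies the medium, the indicator bleaches at 560 nm and transmittance
#' rises. Polarity is an explicit configuration field, never inferred from
#' threshold ordering.
#'
#' @param polarity One of the two strings above.
#' @return The validated polarity string.
#' @export
polarity <- function(polarity = c("growth_decreases_T", "growth_increases_T")) {
  match.arg(polarity)
}

# direction transmittance moves as the culture grows: -1 or +1
.growth_sign <- function(polarity) {
  if (polarity == "growth_increases_T") 1 else -1
}

# has filtered_T crossed `thr` in the growth direction (inclusive)?
.crossed_forward <- function(T_pct, thr, polarity) {
  if (polarity == "growth_increases_T") T_pct >= thr else T_pct <= thr
}

# has T crossed `thr` back in the dilution direction (inclusive)?
.crossed_back <- function(T_pct, thr, polarity) {
  if (polarity == "growth_increases_T") T_pct <= thr else T_pct >= thr
}

#' Operating modes
#'
#' Constructors for the four refresh modes:
#' \describe{
#'   \item{`mode_batch()`}{monitor only; never refreshes.}
#'   \item{`mode_realtime_feedback()`}{turbidostat with a feedback loop: the
#'     culture is refreshed when `trigger_T` is crossed in the growth
#'     direction and dilution continues until `release_T` is crossed back.
#'     Each cycle is capped at `max_cycle_pinch_time` to avoid overflow, with
#'     re-measurement between cycles.}
#'   \item{`mode_threshold_activated()`}{turbidostat without feedback during
#'     the refresh: crossing `trigger_T` runs exactly `n_cycles` calibrated
#'     cycles of `pinch_time` each, then re-arms.}
#'   \item{`mode_time_interval()`}{chemostat: once armed per
#'     `start_condition`, a refresh runs every `period` seconds and is ended
#'     per `stop_condition`.}
#' }
#'
#' @param trigger_T,release_T Percent-transmittance thresholds. For a
#'   phenol-red culture (growth raises T) `trigger_T > release_T`; for a
#'   turbidity culture the opposite.
#' @param max_cycle_pinch_time Per-cycle valve-open cap, seconds.
#' @param pinch_time Valve-open time per cycle, seconds.
#' @param n_cycles Number of cycles run per activation.
#' @param period Seconds between refreshes once armed (> 0).
#' @param start_condition A [start_at_time()] or [start_at_transmittance()].
#' @param stop_condition A [stop_after_pinch_time()] or [stop_at_threshold()].
#' @return A tagged list of class `mode_config`.
#' @name mode_config
NULL

#' @rdname mode_config
#' @export
mode_batch <- function() {
  structure(list(type = "batch"), class = "mode_config")
}

#' @rdname mode_config
#' @export
mode_realtime_feedback <- function(trigger_T, release_T,
                                   max_cycle_pinch_time = 10) {
  stopifnot(is.numeric(trigger_T), is.numeric(release_T),
            max_cycle_pinch_time > 0)
  if (trigger_T == release_T) {
    stop("trigger_T and release_T must differ", call. = FALSE)
  }
  structure(list(type = "realtime_feedback",
                 trigger_T = as.numeric(trigger_T),
                 release_T = as.numeric(release_T),
                 max_cycle_pinch_time = as.numeric(max_cycle_pinch_time)),
            class = "mode_config")
}

#' @rdname mode_config
#' @export
mode_threshold_activated <- function(trigger_T, pinch_time, n_cycles = 1) {
  stopifnot(is.numeric(trigger_T), pinch_time > 0)
  n_cycles <- as.integer(n_cycles)
  stopifnot(n_cycles >= 1L)
  structure(list(type = "threshold_activated",
                 trigger_T = as.numeric(trigger_T),
                 pinch_time = as.numeric(pinch_time), n_cycles = n_cycles),
            class = "mode_config")
}

#' @rdname mode_config
#' @export
mode_time_interval <- function(period, start_condition = start_at_time(0),
                               stop_condition) {
  stopifnot(period > 0, inherits(start_condition, "start_condition"),
            inherits(stop_condition, "stop_condition"))
  structure(list(type = "time_interval", period = as.numeric(period),
                 start_condition = start_condition,
                 stop_condition = stop_condition),
            class = "mode_config")
}

#' Start and stop conditions for the time-interval mode
#'
#' The interval timer either starts at a fixed time or when the signal first
#' crosses a transmittance value in the growth direction; each refresh stops
#' either after a fixed valve-open time or when a transmittance threshold is
#' crossed back.
#'
#' @param time_s Seconds into the run.
#' @param T_pct Percent transmittance.
#' @param pinch_time Total valve-open time per refresh, seconds; split across
#'   several cycles if a single cycle would overflow the vessel.
#' @return Tagged lists of class `start_condition` / `stop_condition`.
#' @name interval_conditions
NULL

#' @rdname interval_conditions
#' @export
start_at_time <- function(time_s) {
  stopifnot(time_s >= 0)
  structure(list(type = "at_time", value = as.numeric(time_s)),
            class = "start_condition")
}

#' @rdname interval_conditions
#' @export
start_at_transmittance <- function(T_pct) {
  structure(list(type = "at_transmittance", value = as.numeric(T_pct)),
            class = "start_condition")
}

#' @rdname interval_conditions
#' @export
stop_after_pinch_time <- function(pinch_time) {
  stopifnot(pinch_time > 0)
  structure(list(type = "after_pinch_time", value = as.numeric(pinch_time)),
            class = "stop_condition")
}

#' @rdname interval_conditions
#' @export
stop_at_threshold <- function(T_pct) {
  structure(list(type = "at_threshold", value = as.numeric(T_pct)),
            class = "stop_condition")
}

#' Control decision for the current sample
#'
#' Pure decision function evaluated once per sample: given the filtered
#' transmittance, the mode, the polarity, and the controller phase, returns
#' one of `"idle"`, `"start_refresh"`, `"continue_refresh"`,
#' `"stop_refresh"`. All threshold comparisons are inclusive, so in
#' noise-free operation the trigger value itself is the recorded extremum.
#'
#' @param filtered_T Filtered percent transmittance (finite).
#' @param mode A [mode_config].
#' @param polarity See [polarity()].
#' @param phase Controller phase: a list with elements `state` (`"idle"` or
#'   `"refreshing"`), and for the stateful modes `cycles_remaining`, `armed`,
#'   `next_due`.
#' @param t Current time, seconds (required by the time-interval mode).
#' @return A decision string.
#' @export
trigger_check <- function(filtered_T, mode, polarity,
                          phase = list(state = "idle"), t = NULL) {
  if (!is.finite(filtered_T)) {
    stop("filtered transmittance must be finite", call. = FALSE)
  }
  stopifnot(inherits(mode, "mode_config"))
  switch(mode$type,
    batch = "idle",
    realtime_feedback = {
      .check_rtf_thresholds(mode, polarity)
      if (identical(phase$state, "refreshing")) {
        if (.crossed_back(filtered_T, mode$release_T, polarity))
          "stop_refresh" else "continue_refresh"
      } else if (.crossed_forward(filtered_T, mode$trigger_T, polarity)) {
        "start_refresh"
      } else "idle"
    },
    threshold_activated = {
      if (identical(phase$state, "refreshing")) {
        if (isTRUE(phase$cycles_remaining > 0L))
          "continue_refresh" else "stop_refresh"
      } else if (.crossed_forward(filtered_T, mode$trigger_T, polarity)) {
        "start_refresh"
      } else "idle"
    },
    time_interval = {
      if (!isTRUE(phase$armed)) return("idle")
      if (is.null(t)) stop("time-interval mode needs the current time",
                           call. = FALSE)
      if (t >= phase$next_due) "start_refresh" else "idle"
    },
    stop("unknown mode type", call. = FALSE))
}

.check_rtf_thresholds <- function(mode, polarity) {
  ok <- if (polarity == "growth_increases_T") {
    mode$trigger_T > mode$release_T
  } else {
    mode$trigger_T < mode$release_T
  }
  if (!ok) {
    stop(sprintf(
      "config error: with polarity '%s', trigger_T (%g) and release_T (%g) are on the wrong sides",
      polarity, mode$trigger_T, mode$release_T), call. = FALSE)
  }
  invisible(TRUE)
}

#' Effective dilution rate of a pulsed refresh schedule
#'
#' A pulse adding `delivered` mL onto `working` mL every `period` seconds
#' dilutes concentrations by working/(working+delivered) per pulse; the exact
#' continuous-equivalent rate is ln((working + delivered)/working) / period,
#' returned per hour. For small pulses this approaches
#' delivered / (working * period).
#'
#' @param period Seconds between pulses (> 0).
#' @param delivered mL added per pulse (>= 0).
#' @param working Working volume, mL (> 0).
#' @return Dilution rate, per hour.
#' @export
effective_dilution_rate <- function(period, delivered, working) {
  stopifnot(period > 0, delivered >= 0, working > 0)
  log((working + delivered) / working) / period * 3600
}

#' Plan the cycles of one refresh
#'
#' Returns a generator: a function that, given the most recent measured
#' transmittance, yields the pinch time (seconds) of the next cycle, or 0
#' when the refresh is complete. Cycles never exceed `max_cycle_pinch_time`,
#' so no single cycle can overflow the vessel; threshold-stopped plans give
#' up after `cycle_cap` cycles with a warning (the stop value may be
#' unreachable, e.g. below the fresh-medium transmittance).
#'
#' @param stop_condition A [stop_after_pinch_time()] or [stop_at_threshold()].
#' @param max_cycle_pinch_time Per-cycle cap, seconds (> 0).
#' @param polarity Required for threshold stops; see [polarity()].
#' @param cycle_cap Maximum number of cycles for threshold stops.
#' @return `function(measured_T = NULL) -> seconds` (0 = done).
#' @export
plan_refresh_cycles <- function(stop_condition, max_cycle_pinch_time,
                                polarity = NULL, cycle_cap = 50) {
  stopifnot(inherits(stop_condition, "stop_condition"),
            max_cycle_pinch_time > 0)
  if (stop_condition$type == "after_pinch_time") {
    remaining <- stop_condition$value
    function(measured_T = NULL) {
      p <- min(remaining, max_cycle_pinch_time)
      remaining <<- remaining - p
      p
    }
  } else {
    stopifnot(!is.null(polarity))
    thr <- stop_condition$value
    done <- 0L
    function(measured_T = NULL) {
      if (!is.null(measured_T) &&
          .crossed_back(measured_T, thr, polarity)) return(0)
      if (done >= cycle_cap) {
        warning(sprintf(
          "refresh stop threshold %g%% not reached after %d cycles; giving up",
          thr, cycle_cap), call. = FALSE)
        return(0)
      }
      done <<- done + 1L
      max_cycle_pinch_time
    }
  }
}

#' Experiment configuration for one channel
#'
#' Bundles everything one continuous-culture channel needs: run duration,
#' acquisition, operating mode, signal polarity, vessel and flow calibration,
#' organism and medium, detector calibration, and the inoculum. Cross-field
#' invariants (threshold ordering vs polarity, pinch times vs overflow
#' headroom) are enforced here.
#'
#' @param duration Run length, hours (> 0).
#' @param acquisition An [acquisition_settings()].
#' @param mode A [mode_config].
#' @param polarity See [polarity()].
#' @param organism An [organism_params()].
#' @param medium A [medium_spec()].
#' @param calibration A [calibration_record()].
#' @param vessel A [vessel_spec()].
#' @param flow A [flow_calibration()].
#' @param inoculum List with `X` (CFU/mL) and optionally `C_acid` for the
#'   starting culture; starting volume is the working volume and starting
#'   substrate is the fresh-medium `S0`.
#' @param channel_id Channel number, 1..3.
#' @param seed Optional integer seed for detector noise, recorded in the log.
#' @param valve_resolution Seconds between in-cycle signal checks while the
#'   valve is open (event-exact stop detection), default 0.05.
#' @param cycle_cap Cycle cap for threshold-stopped refreshes.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(duration, acquisition, mode, polarity,
                              organism, medium, calibration,
                              vessel = vessel_spec(),
                              flow = flow_calibration(),
                              inoculum = list(X = 1e6, C_acid = 0),
                              channel_id = 1, seed = NULL,
                              valve_resolution = 0.05, cycle_cap = 50) {
  stopifnot(duration > 0,
            inherits(acquisition, "acquisition_settings"),
            inherits(mode, "mode_config"),
            inherits(organism, "organism_params"),
            inherits(medium, "medium_spec"),
            inherits(calibration, "calibration_record"),
            inherits(vessel, "vessel_spec"),
            inherits(flow, "flow_calibration"),
            valve_resolution > 0, cycle_cap >= 1)
  polarity <- polarity(polarity)
  channel_id <- as.integer(channel_id)
  if (!channel_id %in% 1:3) {
    stop("channel_id must be 1, 2 or 3", call. = FALSE)
  }
  if (is.null(inoculum$C_acid)) inoculum$C_acid <- 0
  stopifnot(inoculum$X >= 0, inoculum$C_acid >= 0)
  mp <- max_pinch_time(vessel, flow)
  if (mode$type == "realtime_feedback") {
    .check_rtf_thresholds(mode, polarity)
    if (mode$max_cycle_pinch_time > mp) {
      stop(sprintf("max_cycle_pinch_time %g s exceeds the overflow-safe %g s",
                   mode$max_cycle_pinch_time, mp), call. = FALSE)
    }
  }
  if (mode$type == "threshold_activated" && mode$pinch_time > mp) {
    stop(sprintf("pinch_time %g s exceeds the overflow-safe %g s",
                 mode$pinch_time, mp), call. = FALSE)
  }
  structure(list(duration = as.numeric(duration), acquisition = acquisition,
                 mode = mode, polarity = polarity, organism = organism,
                 medium = medium, calibration = calibration, vessel = vessel,
                 flow = flow,
                 inoculum = list(X = as.numeric(inoculum$X),
                                 C_acid = as.numeric(inoculum$C_acid)),
                 channel_id = channel_id,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 valve_resolution = as.numeric(valve_resolution),
                 cycle_cap = as.integer(cycle_cap)),
            class = "experiment_config")
}
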