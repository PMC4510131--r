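# Pinch-valve refresh mechanics: calibrated volume delivery, the two-step
# refresh cycle (dilute, then evacuate excess), and overflow protection.

#' Culture vessel specification
#'
#' @param capacity Maximal liquid capacity, mL (default 55).
#' @param working_volume Volume the controller restores after every refresh
#'   cycle, mL (default 20); must be below capacity so the culture can be
#'   diluted up to about half in a single cycle.
#' @return An object of class `vessel_spec`.
#' @export
vessel_spec <- function(capacity = 55, working_volume = 20) {
  stopifnot(working_volume > 0, capacity > working_volume)
  structure(list(capacity = as.numeric(capacity),
                 working_volume = as.numeric(working_volume)),
            class = "vessel_spec")
}

#' Flow calibration of the medium line
#'
#' Delivery is linear in valve-open (pinch) time above a dead time:
#' volume = rate * max(0, pinch_time - dead_time).
#'
#' @param rate Delivery rate, mL per second (> 0; default 1, the rate the
#'   hardware is adjusted to before an experiment).
#' @param dead_time Seconds of valve opening before liquid arrives (>= 0);
#'   real tubing has lag, and calibration fits an intercept.
#' @return An object of class `flow_calibration`.
#' @export
flow_calibration <- function(rate = 1, dead_time = 0) {
  stopifnot(rate > 0, dead_time >= 0)
  structure(list(rate = as.numeric(rate), dead_time = as.numeric(dead_time)),
            class = "flow_calibration")
}

#' Volume delivered for a given pinch time
#'
#' @param pinch_time Valve-open time, seconds (>= 0); vectorized.
#' @param calib A [flow_calibration()].
#' @return Volume, mL.
#' @export
volume_delivered <- function(pinch_time, calib) {
  if (any(pinch_time < 0)) stop("pinch_time must be >= 0", call. = FALSE)
  calib$rate * pmax(0, pinch_time - calib$dead_time)
}

#' Largest single-cycle pinch time with no overflow
#'
#' (capacity - working_volume) / rate + dead_time: the valve-open time that
#' fills the vessel headroom exactly.
#'
#' @param vessel A [vessel_spec()].
#' @param calib A [flow_calibration()].
#' @return Seconds.
#' @export
max_pinch_time <- function(vessel, calib) {
  (vessel$capacity - vessel$working_volume) / calib$rate + calib$dead_time
}

#' Execute one complete refresh cycle
#'
#' Step A (valve activated): the calibrated volume is added to the culture and
#' mixed. Step B (valve released): the excess above the working volume is
#' evacuated, restoring `working_volume` exactly. Overflow is checked before
#' any state change.
#'
#' @param state A [culture_state()] at working volume.
#' @param pinch_time Valve-open time, seconds.
#' @param medium A [medium_spec()].
#' @param vessel A [vessel_spec()].
#' @param calib A [flow_calibration()].
#' @return A list with elements `state` (the post-cycle [culture_state()]) and
#'   `record` (a one-row data frame: `t_start_s`, `pinch_time_s`,
#'   `volume_added_mL`, `volume_removed_mL`).
#' @export
execute_refresh_cycle <- function(state, pinch_time, medium, vessel, calib) {
  stopifnot(inherits(state, "culture_state"))
  if (abs(state$V - vessel$working_volume) > 1e-9) {
    stop("refresh cycle must start at working volume", call. = FALSE)
  }
  dV <- volume_delivered(pinch_time, calib)
  if (vessel$working_volume + dV > vessel$capacity + 1e-12) {
    stop(sprintf(
      "overflow: delivering %.3f mL onto %.1f mL exceeds the %.1f mL capacity",
      dV, vessel$working_volume, vessel$capacity), call. = FALSE)
  }
  t_start <- state$t * 3600
  state <- mix_in(state, dV, medium)
  state <- draw_off(state, vessel$working_volume)
  list(state = state,
       record = data.frame(t_start_s = t_start,
                           pinch_time_s = as.numeric(pinch_time),
                           volume_added_mL = dV, volume_removed_mL = dV))
}
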