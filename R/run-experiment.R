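# Closed-loop experiment runner: the event loop over the hardware contract,
# and the simulated rig that implements the contract by composing the culture,
# fluidics and optics models.

#' Simulated rig implementing the hardware contract
#'
#' Builds a virtual continuous-culture unit for one channel. The returned
#' environment implements the hardware contract that any real driver must
#' satisfy —
#' \describe{
#'   \item{`read_signal(channel)`}{returns a raw detector reading (with
#'     Gaussian noise if the acquisition settings request it).}
#'   \item{`set_valve(channel, position)`}{`position` is `"normal"` or
#'     `"refresh"`. Returning the valve to `"normal"` evacuates the excess
#'     volume above the working volume (the second step of a refresh cycle).}
#'   \item{`set_mixer(channel, on)`}{no-op in simulation.}
#' }
#' plus two simulation-only members: `advance(dt_s)` and `snapshot()`. While
#' the valve is in `"refresh"` position, `advance()` delivers medium at the
#' calibrated rate (after the dead time) and growth is suspended; valve-open
#' seconds do not advance the culture clock, i.e. delivery is instantaneous
#' on the growth timescale — pinch times of seconds against doubling times of
#' tens of minutes. In `"normal"` position `advance()` integrates growth with
#' fixed-step RK4 (substeps of at most 36 s). `snapshot()` returns the hidden
#' state `c(t_s, V, X, S, C_acid, pH, mu_integral)` for oracle checks.
#'
#' @param config An [experiment_config()].
#' @return An environment implementing the contract above.
#' @export
sim_rig <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  org <- config$organism
  med <- config$medium
  opt <- org$optics
  cal <- config$calibration
  acq <- config$acquisition

  # hidden culture state
  t_s <- 0
  V <- config$vessel$working_volume
  X <- config$inoculum$X
  S <- med$S0
  Ca <- config$inoculum$C_acid
  I <- 0                                  # integral of mu dt (per hour basis)
  valve <- "normal"
  cycle_open <- 0                          # seconds valve has been open
  cum_medium <- 0

  kL <- opt$k_cell * opt$path_length
  span <- cal$blank_signal - cal$dark_signal
  rate <- config$flow$rate
  dead <- config$flow$dead_time
  capacity <- config$vessel$capacity
  working <- config$vessel$working_volume

  pH_now <- function() max(med$pH_floor, med$pH0 - Ca / med$buffer_capacity)

  true_transmittance <- function() {
    A_med <- if (med$phenol_red) {
      frac <- min(1, max(0, (pH_now() - opt$pH_lo) / (opt$pH_hi - opt$pH_lo)))
      opt$phenolred_A_min + frac * (opt$phenolred_A_max - opt$phenolred_A_min)
    } else 0
    100 * 10^(-(kL * X + A_med))
  }

  read_signal <- function(channel = config$channel_id) {
    raw <- cal$dark_signal + true_transmittance() / 100 * span
    if (acq$noise_sd > 0) raw <- raw + stats::rnorm(1L, 0, acq$noise_sd)
    raw
  }

  set_valve <- function(channel = config$channel_id,
                        position = c("normal", "refresh")) {
    position <- match.arg(position)
    if (position == "normal" && valve == "refresh") {
      if (V > working) V <<- working      # well-mixed excess to the trash
      cycle_open <<- 0
    }
    valve <<- position
    invisible(NULL)
  }

  set_mixer <- function(channel = config$channel_id, on = TRUE) invisible(NULL)

  advance <- function(dt_s_step) {
    if (valve == "refresh") {
      prev <- cycle_open
      cycle_open <<- cycle_open + dt_s_step
      dV <- rate * (max(0, cycle_open - dead) - max(0, prev - dead))
      if (dV > 0) {
        if (V + dV > capacity + 1e-12) {
          stop(sprintf(
            "overflow: vessel at %.2f mL cannot take %.3f mL more (capacity %.1f mL)",
            V, dV, capacity), call. = FALSE)
        }
        V_new <- V + dV
        X <<- X * V / V_new
        S <<- (S * V + med$S0 * dV) / V_new
        Ca <<- Ca * V / V_new
        V <<- V_new
        cum_medium <<- cum_medium + dV
      }
    } else {
      n_sub <- max(1L, ceiling(dt_s_step / 36))
      dt_h <- (dt_s_step / 3600) / n_sub
      y <- c(X, S, Ca, I)
      for (i in seq_len(n_sub)) {
        y <- .rk4_monod(y, dt_h, org$mu_max, org$Ks, org$yield_Y, org$q_acid)
      }
      if (any(!is.finite(y))) {
        stop("integration failure: non-finite culture state", call. = FALSE)
      }
      X <<- y[1L]; S <<- y[2L]; Ca <<- max(y[3L], 0); I <<- y[4L]
      t_s <<- t_s + dt_s_step
    }
    invisible(NULL)
  }

  snapshot <- function() {
    c(t_s = t_s, V = V, X = X, S = S, C_acid = Ca, pH = pH_now(),
      mu_integral = I)
  }

  environment()
}

#' Run a closed-loop experiment
#'
#' The controller event loop: every sample period it advances the rig, reads
#' and calibrates the signal, applies the boxcar filter, evaluates the
#' trigger logic of the configured mode, and — when refreshing — executes
#' pinch-valve cycles, monitoring the signal inside each cycle at
#' `valve_resolution` so that threshold-stopped dilutions halt at the
#' crossing. All samples and refresh events are logged; the run terminates at
#' the configured duration. Overflow or hardware faults abort the run and
#' return the partial log with `meta$aborted` set.
#'
#' @param config An [experiment_config()].
#' @param hardware An environment implementing the hardware contract (see
#'   [sim_rig()]); defaults to a simulated rig built from `config`. A real
#'   driver (no `advance` member) is paced against the wall clock.
#' @param keep_state Keep the simulated rig's hidden state trajectory in the
#'   returned log (`$state`); ignored for real hardware.
#' @return An object of class `experiment_log`: list with data frames
#'   `samples` (time_s, channel, raw, transmittance_pct, filtered_pct,
#'   phase), `events` (refresh cycles and mode transitions with volumes),
#'   optionally `state`, and `meta` (config snapshot, seed, version).
#' @export
run_experiment <- function(config, hardware = NULL, keep_state = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  if (is.null(hardware)) hardware <- sim_rig(config)
  simulated <- is.function(hardware$advance)
  advance <- if (simulated) hardware$advance else function(dt) Sys.sleep(dt)
  if (!simulated) keep_state <- FALSE
  if (!is.null(config$seed)) set.seed(config$seed)

  acq <- config$acquisition
  cal <- config$calibration
  mode <- config$mode
  pol <- config$polarity
  ch <- config$channel_id
  sp <- acq$sample_period
  n_avg <- acq$n_average
  dark <- cal$dark_signal
  span <- cal$blank_signal - cal$dark_signal
  slice <- config$valve_resolution
  working <- config$vessel$working_volume
  mp <- max_pinch_time(config$vessel, config$flow)

  n <- floor(config$duration * 3600 / sp)
  time_v <- raw_v <- T_v <- filt_v <- numeric(n)
  phase_v <- integer(n)
  if (keep_state) {
    V_v <- X_v <- S_v <- pH_v <- I_v <- numeric(n)
  }

  # event accumulators
  ev_t <- ev_pinch <- ev_add <- ev_rm <- ev_T <- ev_cum <- numeric(0)
  ev_type <- character(0)
  cum_medium <- 0
  push_event <- function(t, type, pinch = NA_real_, add = NA_real_,
                         rm = NA_real_, T_pct = NA_real_) {
    ev_t <<- c(ev_t, t); ev_type <<- c(ev_type, type)
    ev_pinch <<- c(ev_pinch, pinch); ev_add <<- c(ev_add, add)
    ev_rm <<- c(ev_rm, rm); ev_T <<- c(ev_T, T_pct)
    ev_cum <<- c(ev_cum, cum_medium)
  }

  # boxcar ring buffer
  win <- numeric(n_avg); widx <- 0L; wcount <- 0L; wsum <- 0

  calibrated <- function() {
    100 * (hardware$read_signal(ch) - dark) / span
  }

  # one valve cycle with in-cycle monitoring: open at most cap_s seconds,
  # closing early when the signal crosses `release` back (if non-NULL)
  monitored_cycle <- function(t_now, release, cap_s) {
    hardware$set_valve(ch, "refresh")
    open <- 0; Tm <- NA_real_; stopped <- FALSE
    while (open < cap_s - 1e-9) {
      d <- min(slice, cap_s - open)
      advance(d)
      open <- open + d
      Tm <- calibrated()
      if (!is.null(release) && .crossed_back(Tm, release, pol)) {
        stopped <- TRUE
        break
      }
    }
    hardware$set_valve(ch, "normal")
    dV <- config$flow$rate * max(0, open - config$flow$dead_time)
    cum_medium <<- cum_medium + dV
    push_event(t_now, "refresh_cycle", pinch = open, add = dV, rm = dV,
               T_pct = Tm)
    list(open = open, Tm = Tm, stopped = stopped)
  }

  # plain calibrated cycle (no in-cycle monitoring)
  plain_cycle <- function(t_now, pinch) {
    hardware$set_valve(ch, "refresh")
    advance(pinch)
    hardware$set_valve(ch, "normal")
    dV <- config$flow$rate * max(0, pinch - config$flow$dead_time)
    cum_medium <<- cum_medium + dV
    Tm <- calibrated()
    push_event(t_now, "refresh_cycle", pinch = pinch, add = dV, rm = dV,
               T_pct = Tm)
    Tm
  }

  # controller phase; the loop runs in this frame so that indexed writes to
  # the preallocated log vectors stay in-place
  ph <- "idle"
  cycles_remaining <- 0L
  armed <- FALSE
  next_due <- Inf
  aborted <- NULL
  k_done <- 0L

  tryCatch({
    for (k in seq_len(n)) {
      advance(sp)
      t_now <- k * sp
      raw <- hardware$read_signal(ch)
      T_cal <- 100 * (raw - dark) / span

      widx <- if (widx == n_avg) 1L else widx + 1L
      if (wcount < n_avg) {
        wcount <- wcount + 1L
        wsum <- wsum + T_cal
      } else {
        wsum <- wsum + T_cal - win[widx]
      }
      win[widx] <- T_cal
      filt <- wsum / wcount

      if (mode$type == "realtime_feedback") {
        if (ph == "idle" &&
            .crossed_forward(filt, mode$trigger_T, pol)) {
          ph <- "refreshing"
          push_event(t_now, "trigger", T_pct = filt)
        }
        if (ph == "refreshing") {
          res <- monitored_cycle(t_now, mode$release_T,
                                 mode$max_cycle_pinch_time)
          if (res$stopped) {
            ph <- "idle"
            push_event(t_now, "refresh_stop", T_pct = res$Tm)
          }
        }
      } else if (mode$type == "threshold_activated") {
        if (ph == "idle" &&
            .crossed_forward(filt, mode$trigger_T, pol)) {
          ph <- "refreshing"
          cycles_remaining <- mode$n_cycles
          push_event(t_now, "trigger", T_pct = filt)
        }
        if (ph == "refreshing") {
          plain_cycle(t_now, mode$pinch_time)
          cycles_remaining <- cycles_remaining - 1L
          if (cycles_remaining <= 0L) {
            ph <- "idle"                   # re-arm immediately
            push_event(t_now, "refresh_stop", T_pct = NA_real_)
          }
        }
      } else if (mode$type == "time_interval") {
        if (!armed) {
          sc <- mode$start_condition
          if (sc$type == "at_time" && t_now >= sc$value) {
            armed <- TRUE
            next_due <- sc$value + mode$period
          } else if (sc$type == "at_transmittance" &&
                     .crossed_forward(filt, sc$value, pol)) {
            armed <- TRUE
            next_due <- t_now + mode$period
          }
        }
        if (armed && t_now >= next_due - 1e-9) {
          stopc <- mode$stop_condition
          plan <- plan_refresh_cycles(stopc, mp, pol, config$cycle_cap)
          Tm <- T_cal
          repeat {
            p <- plan(Tm)
            if (p <= 0) break
            if (stopc$type == "at_threshold") {
              res <- monitored_cycle(t_now, stopc$value, p)
              Tm <- res$Tm
              if (res$stopped) break
            } else {
              Tm <- plain_cycle(t_now, p)
            }
          }
          next_due <- next_due + mode$period
        }
      }                                    # batch: nothing to decide

      time_v[k] <- t_now
      raw_v[k] <- raw
      T_v[k] <- T_cal
      filt_v[k] <- filt
      phase_v[k] <- if (ph == "refreshing") 1L else 0L
      if (keep_state) {
        snap <- hardware$snapshot()
        V_v[k] <- snap[["V"]]; X_v[k] <- snap[["X"]]
        S_v[k] <- snap[["S"]]; pH_v[k] <- snap[["pH"]]
        I_v[k] <- snap[["mu_integral"]]
      }
      k_done <- k
    }
  }, error = function(e) {
    aborted <<- conditionMessage(e)
  })

  keep <- seq_len(k_done)
  samples <- data.frame(
    time_s = time_v[keep], channel = rep(ch, k_done), raw = raw_v[keep],
    transmittance_pct = T_v[keep], filtered_pct = filt_v[keep],
    phase = c("idle", "refresh")[phase_v[keep] + 1L])
  events <- data.frame(
    time_s = ev_t, channel = if (length(ev_t)) ch else integer(0),
    event = ev_type, pinch_time_s = ev_pinch, volume_added_mL = ev_add,
    volume_removed_mL = ev_rm, transmittance_pct = ev_T,
    cumulative_medium_mL = ev_cum)
  state <- if (keep_state) {
    data.frame(time_s = time_v[keep], V_mL = V_v[keep], X_cfu_ml = X_v[keep],
               S_g_l = S_v[keep], pH = pH_v[keep], mu_integral = I_v[keep])
  } else NULL

  structure(list(
    samples = samples, events = events, state = state,
    meta = list(
      channel = ch,
      seed = config$seed,
      sample_period_s = sp,
      n_average = n_avg,
      noise_sd = acq$noise_sd,
      polarity = pol,
      mode = unclass(mode)[!vapply(unclass(mode), is.list, logical(1))],
      calibration = list(dark_signal = dark,
                         blank_signal = cal$blank_signal),
      working_volume_mL = working,
      capacity_mL = config$vessel$capacity,
      flow_rate_mL_s = config$flow$rate,
      dead_time_s = config$flow$dead_time,
      duration_h = config$duration,
      software_version = as.character(utils::packageVersion("virtuostat")),
      aborted = aborted),
    config = config),
    class = "experiment_log")
}

#' @export
print.experiment_log <- function(x, ...) {
  m <- x$meta
  cat(sprintf("<experiment_log> channel %d, %s mode, %.3g h, %d samples, %d events\n",
              m$channel, m$mode$type, m$duration_h, nrow(x$samples),
              nrow(x$events)))
  if (!is.null(m$aborted)) cat("  ABORTED:", m$aborted, "\n")
  ncyc <- sum(x$events$event == "refresh_cycle")
  cat(sprintf("  refresh cycles: %d, medium used: %.1f mL\n", ncyc,
              if (nrow(x$events)) max(x$events$cumulative_medium_mL) else 0))
  invisible(x)
}

#' Run several channels of a run configuration
#'
#' Channels are independent culture units; they are executed sequentially,
#' each against its own simulated rig (or supplied hardware), so a
#' three-channel run produces logs identical to three single-channel runs
#' with the same seeds.
#'
#' @param rc A [run_config()] or a list of [experiment_config()] objects.
#' @return A list of [run_experiment()] logs, one per channel.
#' @export
run_channels <- function(rc) {
  channels <- if (inherits(rc, "run_config")) rc$channels else rc
  lapply(channels, run_experiment)
}
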