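# Offline computations on experiment logs: calibration regressions,
# growth-rate estimation, generation accounting, and steady-state summaries.

#' Ordinary least-squares line fit
#'
#' Fits y = slope * x + intercept by least squares (via [stats::lm()]) and
#' reports the Pearson correlation coefficient. Degenerate x (fewer than two
#' distinct values) is an error.
#'
#' @param xs,ys Numeric vectors of equal length (>= 2).
#' @param n_excluded Number of points excluded upstream of the fit (carried
#'   through for reporting).
#' @return An object of class `linear_fit`: slope, intercept, r, r2, n_used,
#'   n_excluded.
#' @export
linear_fit <- function(xs, ys, n_excluded = 0L) {
  stopifnot(length(xs) == length(ys))
  keep <- is.finite(xs) & is.finite(ys)
  xs <- xs[keep]; ys <- ys[keep]
  if (length(unique(xs)) < 2L) {
    stop("fit error: need at least two distinct x values", call. = FALSE)
  }
  fit <- stats::lm(ys ~ xs)
  r <- if (stats::sd(ys) == 0) 0 else stats::cor(xs, ys)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r = r, r2 = r^2, n_used = length(xs),
                 n_excluded = as.integer(n_excluded)),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf(
    "<linear_fit> slope %.6g, intercept %.6g, r2 %.4f (n = %d, excluded %d)\n",
    x$slope, x$intercept, x$r2, x$n_used, x$n_excluded))
  invisible(x)
}

#' Transmittance vs log10 cell density calibration fit
#'
#' The empirical calibration line relating percent transmittance to the
#' logarithm of plate-count cell density. Points with transmittance outside
#' `T_range` are excluded before fitting — outside the exponential window the
#' relation is not linear — and the exclusion count is reported.
#'
#' @param T_pct Percent transmittance readings.
#' @param cfu Cell densities, CFU/mL (> 0).
#' @param T_range Inclusion window `c(low, high)` in percent transmittance;
#'   an explicit, organism-specific judgment.
#' @return A [linear_fit()] of T against log10(CFU/mL).
#' @export
fit_transmittance_vs_logcfu <- function(T_pct, cfu, T_range = c(25, 70)) {
  stopifnot(length(T_pct) == length(cfu), all(cfu > 0), length(T_range) == 2L)
  inside <- T_pct >= T_range[1L] & T_pct <= T_range[2L]
  if (sum(inside) < 2L) {
    stop("fit error: fewer than two points inside the transmittance range",
         call. = FALSE)
  }
  linear_fit(log10(cfu[inside]), T_pct[inside],
             n_excluded = sum(!inside))
}

#' Transmittance vs pH calibration fit (phenol-red window)
#'
#' Fits percent transmittance against pH inside the indicator window where
#' the 560 nm response is linear in pH (about 6 to 7).
#'
#' @param T_pct Percent transmittance readings.
#' @param pH Measured pH values.
#' @param window Inclusion window `c(low, high)` in pH units.
#' @return A [linear_fit()] of T against pH.
#' @export
fit_transmittance_vs_pH <- function(T_pct, pH, window = c(6, 7)) {
  stopifnot(length(T_pct) == length(pH), length(window) == 2L)
  inside <- pH >= window[1L] & pH <= window[2L]
  if (sum(inside) < 2L) {
    stop("fit error: fewer than two points inside the pH window",
         call. = FALSE)
  }
  linear_fit(pH[inside], T_pct[inside], n_excluded = sum(!inside))
}

#' Estimate the specific growth rate from a log interval
#'
#' For a turbidity-monitored culture in exponential growth, absorbance is
#' proportional to cell density, so the slope of ln(absorbance) against time
#' is the specific growth rate. The interval must contain no refresh events
#' (dilution breaks the exponential).
#'
#' @param log An `experiment_log` from [run_experiment()].
#' @param interval `c(t0, t1)` in seconds of log time.
#' @return Specific growth rate, per hour.
#' @export
estimate_growth_rate <- function(log, interval) {
  stopifnot(inherits(log, "experiment_log"), length(interval) == 2L)
  if (!identical(log$meta$polarity, "growth_decreases_T")) {
    stop("growth-rate estimation needs a turbidity-monitored log",
         call. = FALSE)
  }
  ev <- log$events
  refreshes <- ev$time_s[ev$event == "refresh_cycle"]
  if (any(refreshes >= interval[1L] & refreshes <= interval[2L])) {
    stop("interval spans refresh events; pick a refresh-free stretch",
         call. = FALSE)
  }
  s <- log$samples
  inside <- s$time_s >= interval[1L] & s$time_s <= interval[2L]
  if (sum(inside) < 2L) stop("interval contains fewer than two samples",
                             call. = FALSE)
  A <- absorbance_from_transmittance(s$filtered_pct[inside])
  lnA <- base::log(A)           # the `log` argument shadows base::log here
  if (stats::sd(lnA) == 0) return(0)
  t_h <- s$time_s[inside] / 3600
  unname(stats::coef(stats::lm(lnA ~ t_h))[2L])
}

#' Count generations (population doublings) from a log
#'
#' At steady state every dilution is balanced by regrowth, so cumulative
#' doublings equal the cumulative dilution factor in log2: the sum over
#' refresh events of log2((working + volume_added) / working). If the log is
#' not at steady state (start and end filtered transmittance differ by more
#' than `tol` percentage points) the net growth between the endpoints is
#' added as log2 of the absorbance ratio (turbidity logs only, where
#' absorbance is proportional to cell density) and the result is flagged.
#'
#' @param log An `experiment_log`.
#' @param tol Steady-state tolerance in transmittance percentage points.
#' @return Numeric generation count with attributes `steady` (logical) and
#'   `correction` (doublings added by the end-state correction).
#' @export
generations_from_log <- function(log, tol = 1) {
  stopifnot(inherits(log, "experiment_log"))
  W <- log$meta$working_volume_mL
  ev <- log$events
  added <- ev$volume_added_mL[ev$event == "refresh_cycle"]
  gens <- sum(log2((W + added) / W))
  s <- log$samples
  steady <- abs(s$filtered_pct[nrow(s)] - s$filtered_pct[1L]) <= tol
  correction <- 0
  if (!steady) {
    if (!identical(log$meta$polarity, "growth_decreases_T")) {
      stop(paste("log is not at steady state and the end-state correction",
                 "requires a turbidity readout"), call. = FALSE)
    }
    A0 <- absorbance_from_transmittance(s$filtered_pct[1L])
    A1 <- absorbance_from_transmittance(s$filtered_pct[nrow(s)])
    correction <- log2(A1 / A0)
    gens <- gens + correction
    warning("log not at steady state; end-state correction applied",
            call. = FALSE)
  }
  structure(gens, steady = steady, correction = correction)
}

#' Box-and-whisker summary of a steady-state stretch
#'
#' Median and quartiles use linear interpolation between order statistics
#' ([stats::quantile()] type 7); whiskers follow the 1.5 IQR rule, clipped to
#' the most extreme data points inside the fences.
#'
#' @param x Numeric series (e.g. transmittance or CFU samples), or an
#'   `experiment_log` (its filtered transmittance is summarized).
#' @param window Optional `c(t0, t1)` seconds; for a log, restricts to
#'   samples inside the window.
#' @return An object of class `steady_state_summary`: median, q1, q3,
#'   whisker_low, whisker_high, min, max, n.
#' @export
steady_state_summary <- function(x, window = NULL) {
  if (inherits(x, "experiment_log")) {
    s <- x$samples
    if (!is.null(window)) {
      s <- s[s$time_s >= window[1L] & s$time_s <= window[2L], ]
    }
    x <- s$filtered_pct
  } else if (!is.null(window)) {
    stop("a time window only applies to an experiment_log", call. = FALSE)
  }
  x <- x[is.finite(x)]
  if (length(x) < 4L) {
    stop("need at least four samples to summarize", call. = FALSE)
  }
  q <- unname(stats::quantile(x, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3L] - q[1L]
  lo_fence <- q[1L] - 1.5 * iqr
  hi_fence <- q[3L] + 1.5 * iqr
  structure(list(median = q[2L], q1 = q[1L], q3 = q[3L],
                 whisker_low = min(x[x >= lo_fence]),
                 whisker_high = max(x[x <= hi_fence]),
                 min = min(x), max = max(x), n = length(x)),
            class = "steady_state_summary")
}

#' @export
print.steady_state_summary <- function(x, ...) {
  cat(sprintf(
    "<steady_state_summary> n = %d\n  median %.4g [Q1 %.4g, Q3 %.4g], whiskers [%.4g, %.4g], range [%.4g, %.4g]\n",
    x$n, x$median, x$q1, x$q3, x$whisker_low, x$whisker_high, x$min, x$max))
  invisible(x)
}
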