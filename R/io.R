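# Configuration schema (versioned YAML), experiment-log CSV reading/writing
# with a JSON metadata sidecar, and the command-line entry point.

.SCHEMA_VERSION <- 1L

.check_keys <- function(lst, allowed, context) {
  unknown <- setdiff(names(lst), allowed)
  if (length(unknown)) {
    stop(sprintf("unknown key%s in %s: %s", if (length(unknown) > 1) "s" else "",
                 context, paste(unknown, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

.mode_to_list <- function(mode) {
  out <- unclass(mode)
  if (mode$type == "time_interval") {
    out$start_condition <- unclass(mode$start_condition)
    out$stop_condition <- unclass(mode$stop_condition)
  }
  out
}

.mode_from_list <- function(lst) {
  .check_keys(lst, c("type", "trigger_T", "release_T", "max_cycle_pinch_time",
                     "pinch_time", "n_cycles", "period", "start_condition",
                     "stop_condition"), "mode")
  switch(as.character(lst$type),
    batch = mode_batch(),
    realtime_feedback = mode_realtime_feedback(
      lst$trigger_T, lst$release_T,
      if (is.null(lst$max_cycle_pinch_time)) 10 else lst$max_cycle_pinch_time),
    threshold_activated = mode_threshold_activated(
      lst$trigger_T, lst$pinch_time,
      if (is.null(lst$n_cycles)) 1 else lst$n_cycles),
    time_interval = {
      sc <- lst$start_condition
      if (is.null(sc)) sc <- list(type = "at_time", value = 0)
      .check_keys(sc, c("type", "value"), "mode$start_condition")
      st <- lst$stop_condition
      .check_keys(st, c("type", "value"), "mode$stop_condition")
      start <- switch(as.character(sc$type),
        at_time = start_at_time(sc$value),
        at_transmittance = start_at_transmittance(sc$value),
        stop("unknown start_condition type: ", sc$type, call. = FALSE))
      stopc <- switch(as.character(st$type),
        after_pinch_time = stop_after_pinch_time(st$value),
        at_threshold = stop_at_threshold(st$value),
        stop("unknown stop_condition type: ", st$type, call. = FALSE))
      mode_time_interval(lst$period, start, stopc)
    },
    stop("unknown mode type: ", lst$type, call. = FALSE))
}

.channel_to_list <- function(cfg) {
  list(channel_id = cfg$channel_id,
       duration = cfg$duration,
       polarity = cfg$polarity,
       seed = cfg$seed,
       valve_resolution = cfg$valve_resolution,
       cycle_cap = cfg$cycle_cap,
       acquisition = unclass(cfg$acquisition),
       mode = .mode_to_list(cfg$mode),
       vessel = unclass(cfg$vessel),
       flow = unclass(cfg$flow),
       organism = c(unclass(cfg$organism)[c("mu_max", "Ks", "yield_Y",
                                            "q_acid")],
                    list(optics = unclass(cfg$organism$optics))),
       medium = unclass(cfg$medium),
       calibration = unclass(cfg$calibration),
       inoculum = cfg$inoculum)
}

.channel_from_list <- function(lst) {
  .check_keys(lst, c("channel_id", "duration", "polarity", "seed",
                     "valve_resolution", "cycle_cap", "acquisition", "mode",
                     "vessel", "flow", "organism", "medium", "calibration",
                     "inoculum"), "channel")
  need <- c("duration", "polarity", "mode", "organism", "medium",
            "calibration")
  missing <- setdiff(need, names(lst))
  if (length(missing)) {
    stop("channel config missing required field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  .check_keys(lst$acquisition, c("sample_period", "n_average", "noise_sd",
                                 "rng_seed"), "acquisition")
  .check_keys(lst$vessel, c("capacity", "working_volume"), "vessel")
  .check_keys(lst$flow, c("rate", "dead_time"), "flow")
  .check_keys(lst$organism, c("mu_max", "Ks", "yield_Y", "q_acid", "optics",
                              "doubling_time"), "organism")
  .check_keys(lst$organism$optics, c("k_cell", "path_length",
                                     "phenolred_A_min", "phenolred_A_max",
                                     "pH_lo", "pH_hi"), "organism$optics")
  .check_keys(lst$medium, c("S0", "pH0", "buffer_capacity", "phenol_red",
                            "pH_floor"), "medium")
  .check_keys(lst$calibration, c("dark_signal", "blank_signal", "wavelength",
                                 "label"), "calibration")
  .check_keys(lst$inoculum, c("X", "C_acid"), "inoculum")
  org_lst <- lst$organism
  org_lst$doubling_time <- NULL
  optics <- do.call(optical_model_params, org_lst$optics)
  org_lst$optics <- optics
  experiment_config(
    duration = lst$duration,
    acquisition = do.call(acquisition_settings,
                          if (is.null(lst$acquisition)) list()
                          else lst$acquisition),
    mode = .mode_from_list(lst$mode),
    polarity = lst$polarity,
    organism = do.call(organism_params, org_lst),
    medium = do.call(medium_spec, lst$medium),
    calibration = do.call(calibration_record, lst$calibration),
    vessel = if (is.null(lst$vessel)) vessel_spec()
             else do.call(vessel_spec, lst$vessel),
    flow = if (is.null(lst$flow)) flow_calibration()
           else do.call(flow_calibration, lst$flow),
    inoculum = if (is.null(lst$inoculum)) list(X = 1e6) else lst$inoculum,
    channel_id = if (is.null(lst$channel_id)) 1 else lst$channel_id,
    seed = lst$seed,
    valve_resolution = if (is.null(lst$valve_resolution)) 0.05
                       else lst$valve_resolution,
    cycle_cap = if (is.null(lst$cycle_cap)) 50 else lst$cycle_cap)
}

#' Multi-channel run configuration
#'
#' @param channels A list of 1-3 [experiment_config()] objects with unique
#'   channel ids.
#' @param seed Optional global seed recorded with the run.
#' @param output Optional output path prefix.
#' @return An object of class `run_config`.
#' @export
run_config <- function(channels, seed = NULL, output = NULL) {
  if (inherits(channels, "experiment_config")) channels <- list(channels)
  stopifnot(length(channels) >= 1L, length(channels) <= 3L,
            all(vapply(channels, inherits, logical(1), "experiment_config")))
  ids <- vapply(channels, `[[`, integer(1), "channel_id")
  if (anyDuplicated(ids)) {
    stop("channel ids must be unique", call. = FALSE)
  }
  structure(list(schema_version = .SCHEMA_VERSION, channels = channels,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 output = output),
            class = "run_config")
}

#' Save / load a run configuration (YAML)
#'
#' Human-editable structured text with a versioned schema. Loading validates
#' the schema version, rejects unknown keys naming the offending field, fills
#' defaults (55 mL capacity, 20 mL working volume, 1 mL/s flow), and
#' re-enforces every cross-field invariant through the object constructors.
#' `load_config(save_config(x))` reproduces `x` up to YAML numeric precision
#' (15 significant digits).
#'
#' @param rc A [run_config()] or single [experiment_config()].
#' @param path File path for the YAML document.
#' @return `load_config()` returns a [run_config()]; `save_config()` returns
#'   `path` invisibly.
#' @export
save_config <- function(rc, path) {
  if (inherits(rc, "experiment_config")) rc <- run_config(list(rc))
  stopifnot(inherits(rc, "run_config"))
  doc <- list(schema_version = rc$schema_version,
              seed = rc$seed, output = rc$output,
              channels = lapply(rc$channels, .channel_to_list))
  doc <- doc[!vapply(doc, is.null, logical(1))]
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  .check_keys(doc, c("schema_version", "seed", "output", "channels"),
              "run config")
  if (is.null(doc$schema_version) ||
      doc$schema_version != .SCHEMA_VERSION) {
    stop(sprintf("unsupported schema_version '%s' (this build reads %d)",
                 doc$schema_version, .SCHEMA_VERSION), call. = FALSE)
  }
  if (is.null(doc$channels) || !length(doc$channels)) {
    stop("config has no channels", call. = FALSE)
  }
  run_config(lapply(doc$channels, .channel_from_list),
             seed = doc$seed, output = doc$output)
}

.LOG_COLUMNS <- c("time_s", "channel", "raw", "transmittance_pct",
                  "filtered_pct", "phase", "event", "pinch_time_s",
                  "volume_added_mL", "volume_removed_mL",
                  "cumulative_medium_mL")

#' Write / read an experiment log (CSV + JSON sidecar)
#'
#' One fixed-dialect CSV (header row, '.' decimal, UTF-8) holds sample and
#' event rows interleaved in time order; event rows carry a non-empty `event`
#' column, sample rows leave it empty. Numbers are written at full double
#' precision so `read_log(write_log(x))` reproduces `x` field for field. Run
#' metadata goes to a `<path>.meta.json` sidecar.
#'
#' @param log An `experiment_log` from [run_experiment()].
#' @param path CSV file path.
#' @return `write_log()` returns `path` invisibly; `read_log()` returns an
#'   `experiment_log` (without the in-memory `state` table, which is not
#'   serialized).
#' @export
write_log <- function(log, path) {
  stopifnot(inherits(log, "experiment_log"))
  s <- log$samples
  srows <- data.frame(time_s = s$time_s, channel = s$channel, raw = s$raw,
                      transmittance_pct = s$transmittance_pct,
                      filtered_pct = s$filtered_pct, phase = s$phase,
                      event = rep(NA_character_, nrow(s)),
                      pinch_time_s = rep(NA_real_, nrow(s)),
                      volume_added_mL = rep(NA_real_, nrow(s)),
                      volume_removed_mL = rep(NA_real_, nrow(s)),
                      cumulative_medium_mL = rep(NA_real_, nrow(s)))
  e <- log$events
  erows <- data.frame(time_s = e$time_s, channel = e$channel,
                      raw = rep(NA_real_, nrow(e)),
                      transmittance_pct = e$transmittance_pct,
                      filtered_pct = rep(NA_real_, nrow(e)),
                      phase = rep(NA_character_, nrow(e)),
                      event = e$event, pinch_time_s = e$pinch_time_s,
                      volume_added_mL = e$volume_added_mL,
                      volume_removed_mL = e$volume_removed_mL,
                      cumulative_medium_mL = e$cumulative_medium_mL)
  all_rows <- rbind(srows, erows)
  # stable time order, events after the sample of the same instant
  key <- c(rep(0L, nrow(srows)), rep(1L, nrow(erows)))
  ord <- order(all_rows$time_s, key)
  all_rows <- all_rows[ord, , drop = FALSE]
  num <- vapply(all_rows, is.numeric, logical(1))
  out <- all_rows
  for (j in which(num)) {
    out[[j]] <- ifelse(is.na(all_rows[[j]]), "",
                       sprintf("%.17g", all_rows[[j]]))
  }
  out$channel <- as.character(all_rows$channel)
  out[is.na(out)] <- ""
  utils::write.table(out, path, sep = ",", quote = FALSE, na = "",
                     row.names = FALSE, fileEncoding = "UTF-8")
  jsonlite::write_json(log$meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_log
#' @export
read_log <- function(path) {
  if (!file.exists(path)) stop("log file not found: ", path, call. = FALSE)
  raw_tab <- utils::read.csv(path, colClasses = "character",
                             fileEncoding = "UTF-8")
  missing <- setdiff(.LOG_COLUMNS, names(raw_tab))
  if (length(missing)) {
    stop("malformed log: missing column(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  num_cols <- setdiff(.LOG_COLUMNS, c("phase", "event"))
  for (col in num_cols) {
    v <- raw_tab[[col]]
    parsed <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & v != "" & is.na(parsed))
    if (length(bad)) {
      stop(sprintf("malformed log: line %d, column %s: cannot parse '%s'",
                   bad[1L] + 1L, col, v[bad[1L]]), call. = FALSE)
    }
    parsed[v == ""] <- NA_real_
    raw_tab[[col]] <- parsed
  }
  raw_tab$event[raw_tab$event == ""] <- NA_character_
  raw_tab$phase[raw_tab$phase == ""] <- NA_character_
  is_event <- !is.na(raw_tab$event)
  samples <- raw_tab[!is_event, c("time_s", "channel", "raw",
                                  "transmittance_pct", "filtered_pct",
                                  "phase")]
  samples$channel <- as.integer(samples$channel)
  rownames(samples) <- NULL
  events <- raw_tab[is_event, c("time_s", "channel", "event", "pinch_time_s",
                                "volume_added_mL", "volume_removed_mL",
                                "transmittance_pct", "cumulative_medium_mL")]
  events$channel <- as.integer(events$channel)
  rownames(events) <- NULL
  sidecar <- paste0(path, ".meta.json")
  meta <- if (file.exists(sidecar)) {
    jsonlite::read_json(sidecar, simplifyVector = TRUE)
  } else list()
  structure(list(samples = samples, events = events, state = NULL,
                 meta = meta, config = NULL),
            class = "experiment_log")
}
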