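# Readers and writers for the stream CSV, episode/event/truth TSV and the
# JSON records. All times are seconds, numbers are written with 6 decimal
# places; files are UTF-8 with '.' as decimal separator.

.STREAM_HEADER <- c("t", paste0("L", 1:6), paste0("R", 1:6))

.check_file <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cannot open '%s': no such file", path), call. = FALSE)
  }
  invisible(path)
}

#' Write a bilateral recording to the stream CSV dialect
#'
#' Columns `t,L1..L6,R1..R6`: time in seconds with 6 decimals, sensor bits
#' as 0/1.
#'
#' @param x A [fog_recording()] holding insole streams, or a list with
#'   `left` and `right` [insole_stream()]s.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stream <- function(x, path) {
  if (inherits(x, "fog_recording")) {
    if (is.null(x$streams)) {
      stop("recording carries no per-sensor streams to write", call. = FALSE)
    }
    x <- x$streams
  }
  left <- x$left; right <- x$right
  stopifnot(inherits(left, "insole_stream"), inherits(right, "insole_stream"))
  if (nrow(left$bits) != nrow(right$bits) ||
      abs(left$sampling_rate - right$sampling_rate) > 1e-9) {
    stop("alignment error: left/right streams differ", call. = FALSE)
  }
  n <- nrow(left$bits)
  tt <- left$t0 + (seq_len(n) - 1L) / left$sampling_rate
  df <- data.frame(t = sprintf("%.6f", tt), left$bits, right$bits)
  names(df) <- .STREAM_HEADER
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a bilateral recording from the stream CSV dialect
#'
#' Validates the header, that every sensor value is 0 or 1, and that `t`
#' is strictly increasing with `1/sampling_rate` spacing (tolerance 1e-6
#' s); violations raise format errors naming the offending row.
#'
#' @param path Input file path.
#' @param sampling_rate Expected sampling rate in Hz (default 32).
#' @return A [fog_recording()] carrying the left and right
#'   [insole_stream()]s.
#' @export
read_stream <- function(path, sampling_rate = 32) {
  .check_file(path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!identical(names(df), .STREAM_HEADER)) {
    stop(sprintf("format error: expected header '%s'",
                 paste(.STREAM_HEADER, collapse = ",")), call. = FALSE)
  }
  if (nrow(df) < 1L) stop("format error: empty stream", call. = FALSE)
  bits <- as.matrix(df[, -1L])
  bad <- which(!(bits %in% c(0, 1)))
  if (length(bad)) {
    row <- ((bad[1L] - 1L) %% nrow(bits)) + 1L
    stop(sprintf("format error: non-binary sensor value at row %d", row),
         call. = FALSE)
  }
  dt <- 1 / sampling_rate
  if (nrow(df) > 1L) {
    gaps <- diff(df$t)
    bad <- which(abs(gaps - dt) > 1e-6)
    if (length(bad)) {
      stop(sprintf("format error: irregular time spacing at row %d (got %.6f, expected %.6f)",
                   bad[1L] + 1L, gaps[bad[1L]], dt), call. = FALSE)
    }
  }
  t0 <- df$t[1L]
  left <- insole_stream(bits[, 1:6, drop = FALSE], "left", sampling_rate, t0)
  right <- insole_stream(bits[, 7:12, drop = FALSE], "right", sampling_rate, t0)
  fog_recording(left, right)
}

#' Write phase episodes to TSV
#'
#' Columns `phase,foot,start_s,end_s,duration_s,truncated`.
#'
#' @param episodes A `phase_episodes` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_episodes <- function(episodes, path) {
  df <- as.data.frame(episodes)[, c("phase", "foot", "start_s", "end_s",
                                    "duration_s", "truncated")]
  for (col in c("start_s", "end_s", "duration_s")) df[[col]] <- sprintf("%.6f", df[[col]])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read ground-truth FoG labels from TSV
#'
#' Columns `start_s,end_s,kind`; rows are returned sorted by start and
#' validated (known kinds, well-formed non-overlapping intervals).
#'
#' @param path Input file path.
#' @return A [truth_labels()] data frame.
#' @export
read_truth <- function(path) {
  .check_file(path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("start_s", "end_s", "kind") %in% names(df))) {
    stop("format error: truth TSV needs columns start_s, end_s, kind",
         call. = FALSE)
  }
  as_truth_labels(df)
}

#' Write ground-truth FoG labels to TSV
#' @param truth A [truth_labels()] table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  truth <- as_truth_labels(truth)
  df <- data.frame(start_s = sprintf("%.6f", truth$start_s),
                   end_s = sprintf("%.6f", truth$end_s),
                   kind = truth$kind)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write detected FoG events to TSV
#'
#' Columns `kind,start_s,end_s,onset_s`.
#'
#' @param events A `fog_events` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  df <- as.data.frame(events)
  if (is.null(df$onset_s)) df$onset_s <- df$start_s
  if (is.null(df$end_s)) df$end_s <- pmax(df$start_s, df$onset_s)
  out <- data.frame(kind = df$kind,
                    start_s = sprintf("%.6f", df$start_s),
                    end_s = sprintf("%.6f", df$end_s),
                    onset_s = sprintf("%.6f", df$onset_s))
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read detected FoG events from TSV
#' @param path Input file path.
#' @return A `fog_events` data frame (`kind,start_s,end_s,onset_s`).
#' @export
read_events <- function(path) {
  .check_file(path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("kind", "start_s", "end_s", "onset_s")
  if (!all(need %in% names(df))) {
    stop("format error: event TSV needs columns kind, start_s, end_s, onset_s",
         call. = FALSE)
  }
  bad <- setdiff(unique(df$kind), c("LDDS", "SSW_L", "SSW_R"))
  if (length(bad)) {
    stop(sprintf("format error: unknown event kind '%s'", bad[1L]), call. = FALSE)
  }
  df <- df[order(df$start_s), need, drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("fog_events", class(df))
  df
}

#' Write / read a calibration profile as JSON
#'
#' Field names match the in-memory object exactly: `baseline_ds`,
#' `baseline_sw`, `baseline_sw_recip`, `n_ds`, `n_sw`.
#'
#' @param profile A [calibration_profile()].
#' @param path File path.
#' @return `write_profile` returns `path` invisibly; `read_profile`
#'   returns a [calibration_profile()].
#' @export
write_profile <- function(profile, path) {
  .check_profile(profile)
  jsonlite::write_json(unclass(profile), path, auto_unbox = TRUE, digits = 6)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  .check_file(path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_profile(baseline_ds = x$baseline_ds, baseline_sw = x$baseline_sw,
                      n_ds = x$n_ds, n_sw = x$n_sw)
}

#' Write / read detection thresholds as JSON
#'
#' Field names: `k_ds`, `k_sw`, `m_sw`, `merge_gap`.
#'
#' @param thresholds A [detection_thresholds()].
#' @param path File path.
#' @return `write_thresholds` returns `path` invisibly; `read_thresholds`
#'   returns a [detection_thresholds()].
#' @export
write_thresholds <- function(thresholds, path) {
  stopifnot(inherits(thresholds, "detection_thresholds"))
  jsonlite::write_json(unclass(thresholds), path, auto_unbox = TRUE, digits = 6)
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  .check_file(path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  detection_thresholds(k_ds = x$k_ds, k_sw = x$k_sw, m_sw = x$m_sw,
                       merge_gap = x$merge_gap)
}

#' Run configuration
#'
#' Bundle of the tunable run parameters with their reference defaults:
#' the published threshold multipliers (k_ds 4.7, k_sw 4.5), 8-sample
#' packets, 0.5 s evaluation tolerance, the 30 s cueing hold, and the
#' auditory cue rhythm factor of 1.1 times the wearer's normal walking
#' rhythm (metadata: audio playback is outside this package).
#'
#' @param sampling_rate Hz.
#' @param thresholds A [detection_thresholds()].
#' @param packet_size Samples per transport packet.
#' @param eval_tol Event-matching tolerance, seconds.
#' @param cueing_hold_s Continuous-normal-gait hold before cueing stops.
#' @param cue_rhythm_factor Cue rhythm relative to normal walking rhythm.
#' @param seed Integer seed.
#' @param sim Optional list of [sim_config()] arguments.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(sampling_rate = 32,
                       thresholds = detection_thresholds(),
                       packet_size = 8, eval_tol = 0.5, cueing_hold_s = 30,
                       cue_rhythm_factor = 1.1, seed = 1, sim = NULL) {
  stopifnot(sampling_rate > 0, inherits(thresholds, "detection_thresholds"),
            packet_size >= 1, eval_tol >= 0, cueing_hold_s >= 0,
            cue_rhythm_factor > 0)
  if (!is.null(sim)) sim <- do.call(sim_config, sim)
  structure(list(sampling_rate = sampling_rate, thresholds = thresholds,
                 packet_size = as.integer(packet_size), eval_tol = eval_tol,
                 cueing_hold_s = cueing_hold_s,
                 cue_rhythm_factor = cue_rhythm_factor,
                 seed = as.integer(seed), sim = sim),
            class = "run_config")
}

#' Write / read a run configuration as JSON
#'
#' Unknown keys in the file are rejected on load.
#'
#' @param config A [run_config()].
#' @param path File path.
#' @return `write_config` returns `path` invisibly; `read_config` returns
#'   a validated [run_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$thresholds <- unclass(x$thresholds)
  if (!is.null(x$sim)) {
    x$sim <- unclass(x$sim)
    # keep the names: jsonlite writes named vectors as bare arrays
    x$sim$manifestation_mix <- as.list(x$sim$manifestation_mix)
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 8, null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  .check_file(path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("sampling_rate", "thresholds", "packet_size", "eval_tol",
             "cueing_hold_s", "cue_rhythm_factor", "seed", "sim")
  unknown <- setdiff(names(x), known)
  if (length(unknown)) {
    stop(sprintf("validation error: unknown config key '%s'", unknown[1L]),
         call. = FALSE)
  }
  if (!is.null(x$thresholds)) {
    tk <- setdiff(names(x$thresholds), c("k_ds", "k_sw", "m_sw", "merge_gap"))
    if (length(tk)) {
      stop(sprintf("validation error: unknown thresholds key '%s'", tk[1L]),
           call. = FALSE)
    }
    x$thresholds <- do.call(detection_thresholds, x$thresholds)
  }
  if (!is.null(x$sim)) {
    x$sim$manifestation_mix <- unlist(x$sim$manifestation_mix)
    x$sim <- lapply(x$sim, function(v) if (is.list(v)) unlist(v) else v)
  }
  do.call(run_config, x)
}

#' Write an evaluation report as JSON
#'
#' Layout: `{sensitivity, specificity, accuracy, correct_pct, over_pct,
#' under_pct, latency: {kind: {mean, min, max}}}`.
#'
#' @param eval A `fog_eval` from [evaluate_events()].
#' @param latency Optional `latency_summary` from [latency_stats()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(eval, latency = NULL, path) {
  stopifnot(inherits(eval, "fog_eval"))
  lat <- list()
  if (!is.null(latency) && nrow(latency)) {
    for (i in seq_len(nrow(latency))) {
      lat[[latency$kind[i]]] <- list(mean = latency$mean_s[i],
                                     min = latency$min_s[i],
                                     max = latency$max_s[i])
    }
  }
  out <- list(sensitivity = eval$metrics$sensitivity,
              specificity = eval$metrics$specificity,
              accuracy = eval$metrics$accuracy,
              correct_pct = eval$accounting$correct_pct,
              over_pct = eval$accounting$over_pct,
              under_pct = eval$accounting$under_pct,
              latency = lat)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = 6, null = "null")
  invisible(path)
}

#' Write a streaming decision log as JSON lines
#'
#' One JSON record per announced onset:
#' `{kind, onset_s, decision_time, latency_s}`.
#'
#' @param log A `stream_log` from [stream_detect()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_stream_log <- function(log, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(log))) {
    writeLines(jsonlite::toJSON(list(kind = log$kind[i],
                                     onset_s = log$onset_s[i],
                                     decision_time = log$decision_time[i],
                                     latency_s = log$latency_s[i]),
                                auto_unbox = TRUE, digits = 6), con)
  }
  invisible(path)
}
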