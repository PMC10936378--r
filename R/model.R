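# The fog_detector modelling interface: calibrate (+ optionally train) on a
# recording, then predict on new recordings.

# First `end_s` seconds of a combined signal.
.crop_signal <- function(cs, end_s) {
  n <- min(length(cs$bits), as.integer(round(end_s * cs$sampling_rate)))
  if (n < 2L) stop("calibration window too short", call. = FALSE)
  combine_signal(cs$bits[seq_len(n)], foot = cs$foot,
                 sampling_rate = cs$sampling_rate, t0 = cs$t0)
}

#' Fit a freezing-of-gait detector
#'
#' Calibrates per-user baseline phase durations on a FoG-free walk and,
#' when labelled training data are supplied, trains the ratio thresholds
#' `k_ds` and `k_sw` by maximising sensitivity + specificity over the
#' fuzzy zone; otherwise the published reference defaults (4.7, 4.5) are
#' kept. The fitted object predicts FoG events on new recordings, offline
#' or through the packetized streaming path.
#'
#' @param calibration A [fog_recording()] of FoG-free walking (straight
#'   lines and turns), or one with a labelled clean leading window (see
#'   `calibration_window_s`).
#' @param training Optional labelled training data: a [fog_recording()]
#'   with `truth`, or a list of them. Used to train the thresholds.
#' @param thresholds Starting [detection_thresholds()] (also supplies
#'   `m_sw` and `merge_gap` for trained fits).
#' @param calibration_window_s Restrict calibration to the first so many
#'   seconds of `calibration` (e.g. 30 for recordings whose leading window
#'   is episode-free); `NULL` uses the whole recording.
#' @param min_episodes Minimum episode counts for [calibrate()].
#' @param grid_step Threshold-training grid resolution.
#' @return An object of class `fog_detector` with elements `profile`,
#'   `thresholds`, `fits` (per-kind `threshold_fit`s or `NULL`), `trained`,
#'   `sampling_rate` and `call`.
#' @seealso [predict.fog_detector()], [calibrate()],
#'   [train_detection_thresholds()], [detect_fog_offline()]
#' @examples
#' sim <- simulate_recording(sim_config(duration_s = 90, seed = 3))
#' det <- fog_detector(sim$recording, calibration_window_s = 30)
#' predict(det, sim$recording)$events
#' @export
fog_detector <- function(calibration, training = NULL,
                         thresholds = detection_thresholds(),
                         calibration_window_s = NULL, min_episodes = 8,
                         grid_step = 0.1) {
  stopifnot(inherits(calibration, "fog_recording"))
  left <- calibration$left
  right <- calibration$right
  if (!is.null(calibration_window_s)) {
    left <- .crop_signal(left, calibration_window_s)
    right <- .crop_signal(right, calibration_window_s)
  }
  profile <- calibrate(left, right, min_episodes = min_episodes)
  fits <- NULL
  trained <- FALSE
  if (!is.null(training)) {
    if (inherits(training, "fog_recording")) training <- list(training)
    inst <- do.call(rbind, lapply(training, function(rec) {
      stopifnot(inherits(rec, "fog_recording"))
      if (is.null(rec$truth)) {
        stop("training recordings must carry truth labels", call. = FALSE)
      }
      build_instances(segment_phases(rec$left, rec$right), rec$truth, profile)
    }))
    thresholds <- train_detection_thresholds(inst, grid_step = grid_step,
                                             m_sw = thresholds$m_sw,
                                             merge_gap = thresholds$merge_gap)
    fits <- list(ds = attr(thresholds, "fit_ds"), sw = attr(thresholds, "fit_sw"))
    trained <- TRUE
  }
  structure(list(profile = profile, thresholds = thresholds, fits = fits,
                 trained = trained,
                 sampling_rate = calibration$left$sampling_rate,
                 call = match.call()),
            class = "fog_detector")
}

#' @export
print.fog_detector <- function(x, ...) {
  cat("Freezing-of-gait detector\n")
  cat(sprintf("  baselines: double support %.4f s, swing %.4f s\n",
              x$profile$baseline_ds, x$profile$baseline_sw))
  cat(sprintf("  thresholds: k_ds = %g, k_sw = %g (%s)\n",
              x$thresholds$k_ds, x$thresholds$k_sw,
              if (x$trained) "trained" else "reference defaults"))
  invisible(x)
}

#' @export
summary.fog_detector <- function(object, ...) {
  dt <- 1 / object$sampling_rate
  out <- list(
    profile = object$profile,
    thresholds = object$thresholds,
    ldds_bound_s = object$thresholds$k_ds * object$profile$baseline_ds,
    short_swing_bound_s = object$profile$baseline_sw / object$thresholds$k_sw,
    ldds_detection_delay_s =
      ceiling(object$thresholds$k_ds * object$profile$baseline_ds / dt - 1e-9) * dt,
    trained = object$trained, fits = object$fits
  )
  class(out) <- "summary.fog_detector"
  out
}

#' @export
print.summary.fog_detector <- function(x, ...) {
  cat("Freezing-of-gait detector\n")
  cat(sprintf("  baseline double support : %.4f s (n = %d)\n",
              x$profile$baseline_ds, x$profile$n_ds))
  cat(sprintf("  baseline swing          : %.4f s (n = %d)\n",
              x$profile$baseline_sw, x$profile$n_sw))
  cat(sprintf("  k_ds = %g -> long-double-support bound %.4f s (online delay %.5f s)\n",
              x$thresholds$k_ds, x$ldds_bound_s, x$ldds_detection_delay_s))
  cat(sprintf("  k_sw = %g -> short-swing bound %.4f s, m_sw = %d\n",
              x$thresholds$k_sw, x$short_swing_bound_s, x$thresholds$m_sw))
  if (x$trained) {
    cat(sprintf("  trained: k_ds zone [%.3f, %.3f], k_sw zone [%.3f, %.3f]\n",
                x$fits$ds$zone$low, x$fits$ds$zone$high,
                x$fits$sw$zone$low, x$fits$sw$zone$high))
  }
  invisible(x)
}

#' @export
coef.fog_detector <- function(object, ...) {
  c(k_ds = object$thresholds$k_ds, k_sw = object$thresholds$k_sw,
    baseline_ds_s = object$profile$baseline_ds,
    baseline_sw_s = object$profile$baseline_sw)
}

#' Predict FoG events on a new recording
#'
#' @param object A fitted [fog_detector()].
#' @param newdata A [fog_recording()].
#' @param type `"events"` for the offline [detect_fog_offline()] result,
#'   `"onsets"` for sample-by-sample online onsets, or `"stream"` for the
#'   packetized streaming log with decision times.
#' @param packet_size,transmission_delay Streaming-path parameters.
#' @param ... Unused.
#' @return See the respective engine: a `fog_detection`, an onset data
#'   frame, or a `stream_log`.
#' @export
predict.fog_detector <- function(object, newdata,
                                 type = c("events", "onsets", "stream"),
                                 packet_size = 8, transmission_delay = 0, ...) {
  type <- match.arg(type)
  stopifnot(inherits(newdata, "fog_recording"))
  switch(type,
    events = detect_fog_offline(newdata, profile = object$profile,
                                thresholds = object$thresholds),
    onsets = detect_onsets_online(newdata, profile = object$profile,
                                  thresholds = object$thresholds),
    stream = stream_detect(packetize(newdata, packet_size = packet_size,
                                     transmission_delay = transmission_delay),
                           object$profile, object$thresholds)
  )
}

#' Simulate recordings that emulate the fitted wearer
#'
#' Generates synthetic labelled recordings whose clean-gait double-support
#' and swing means are set to the detector's calibrated baselines, so that
#' the simulated wearer walks (approximately) like the calibrated one.
#'
#' @param object A [fog_detector()].
#' @param nsim Number of recordings.
#' @param seed Integer seed of the first recording (subsequent ones use
#'   `seed + 1`, ...).
#' @param duration_s,fog_rate Passed to [sim_config()].
#' @param ... Further [sim_config()] arguments.
#' @return A list of `fog_sim` objects (length `nsim`).
#' @export
simulate.fog_detector <- function(object, nsim = 1, seed = 1,
                                  duration_s = 180, fog_rate = 2, ...) {
  lapply(seq_len(nsim), function(i) {
    cfg <- sim_config(duration_s = duration_s, fog_rate = fog_rate,
                      ds_mean = object$profile$baseline_ds,
                      swing_mean = object$profile$baseline_sw,
                      sampling_rate = object$sampling_rate,
                      seed = seed + i - 1L, ...)
    simulate_recording(cfg)
  })
}

#' Plot a recording with detected and true FoG events
#'
#' Draws the left and right combined signals as step traces with the
#' ground-truth intervals (grey) and detected events (red) shaded, and
#' detection onsets marked.
#'
#' @param x A [fog_recording()].
#' @param detection Optional `fog_detection` from [detect_fog_offline()].
#' @param xlim Optional time window in seconds.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.fog_recording <- function(x, detection = NULL, xlim = NULL, ...) {
  n <- length(x$left$bits)
  tt <- x$left$t0 + (seq_len(n) - 1L) / x$left$sampling_rate
  if (is.null(xlim)) xlim <- range(tt)
  graphics::plot(NA, xlim = xlim, ylim = c(-0.2, 3.4), xlab = "time (s)",
                 ylab = "", yaxt = "n", ...)
  graphics::axis(2, at = c(0.5, 2.5), labels = c("right", "left"), las = 1)
  shade <- function(from, to, col) {
    graphics::rect(from, -0.2, to, 3.4, col = col, border = NA)
  }
  if (!is.null(x$truth) && nrow(x$truth)) {
    shade(x$truth$start_s, x$truth$end_s, grDevices::adjustcolor("grey40", 0.25))
  }
  if (!is.null(detection) && nrow(detection$events)) {
    ev <- detection$events
    shade(ev$start_s, ev$end_s, grDevices::adjustcolor("red", 0.18))
    graphics::abline(v = ev$onset_s, col = "red", lty = 3)
  }
  graphics::lines(tt, x$left$bits + 2.2, type = "s", col = "navy")
  graphics::lines(tt, x$right$bits + 0.2, type = "s", col = "darkgreen")
  invisible(x)
}

#' @export
plot.fog_detector <- function(x, newdata, ...) {
  det <- predict(x, newdata, type = "events")
  plot(newdata, detection = det, ...)
}
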