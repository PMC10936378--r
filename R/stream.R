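# Packetized transport model, streaming detection and the cueing controller.

#' Packetization period
#'
#' The insoles transmit samples in fixed-size packets over Bluetooth; a
#' sample captured just after a packet closes waits a full packet for
#' delivery, so packetization induces a response-time variation spanning
#' `packet_size / sampling_rate` seconds (0.25 s at the default 8 samples
#' per packet and 32 Hz).
#'
#' @param packet_size Samples per packet (>= 1).
#' @param sampling_rate Hz (> 0).
#' @return The packet period in seconds.
#' @examples
#' packet_period(8, 32)   # 0.25
#' @export
packet_period <- function(packet_size = 8, sampling_rate = 32) {
  if (!is.numeric(packet_size) || packet_size < 1) {
    stop("parameter error: `packet_size` must be >= 1", call. = FALSE)
  }
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop("parameter error: `sampling_rate` must be > 0 Hz", call. = FALSE)
  }
  packet_size / sampling_rate
}

#' Packetize a bilateral recording
#'
#' Groups aligned bilateral samples into consecutive non-overlapping
#' packets of `packet_size` samples; a trailing partial packet is delivered
#' at stream end rather than dropped, so streaming detection sees every
#' sample of a finite recording. Each packet is delivered at the capture
#' time of its last sample plus `transmission_delay`; a sample's
#' availability delay (delivery minus capture) therefore lies in
#' `[transmission_delay, (packet_size - 1)/Fs + transmission_delay]`.
#'
#' @param left,right Aligned [combined_signal()]s or [insole_stream()]s,
#'   or a [fog_recording()] as `left`.
#' @param packet_size Samples per packet (default 8).
#' @param transmission_delay Radio delay added to every delivery, seconds
#'   (default 0).
#' @return A list of class `packet_stream`; each element has `first`
#'   (0-based index of its first sample), `left`/`right` (bit vectors),
#'   `capture_times` and `delivery_time`.
#' @export
packetize <- function(left, right = NULL, packet_size = 8,
                      transmission_delay = 0) {
  if (inherits(left, "fog_recording")) {
    right <- left$right
    left <- left$left
  }
  if (inherits(left, "insole_stream")) left <- combine_signal(left)
  if (inherits(right, "insole_stream")) right <- combine_signal(right)
  .check_aligned(left, right)
  if (!is.numeric(packet_size) || packet_size < 1) {
    stop("parameter error: `packet_size` must be >= 1", call. = FALSE)
  }
  packet_size <- as.integer(packet_size)
  n <- length(left$bits)
  dt <- 1 / left$sampling_rate
  starts <- seq.int(0L, n - 1L, by = packet_size)
  packets <- lapply(starts, function(s) {
    idx <- seq.int(s, min(s + packet_size, n) - 1L)
    list(first = s,
         left = left$bits[idx + 1L],
         right = right$bits[idx + 1L],
         capture_times = left$t0 + idx * dt,
         delivery_time = left$t0 + idx[length(idx)] * dt + transmission_delay)
  })
  structure(packets, class = "packet_stream",
            sampling_rate = left$sampling_rate, t0 = left$t0,
            packet_size = packet_size, transmission_delay = transmission_delay)
}

#' Streaming FoG detection through the packet model
#'
#' Replays a packetized recording through the online onset detector in
#' delivery order. Packetization changes decision times but never
#' decisions: the announced event set is identical to sample-by-sample
#' streaming and to [detect_fog_offline()]. Each announced onset carries a
#' `decision_time`, the moment the triggering sample became available:
#' `max(onset_s, delivery time of its packet)`.
#'
#' @param packets A `packet_stream` from [packetize()], or a
#'   [fog_recording()] (packetized with the defaults).
#' @param profile A [calibration_profile()].
#' @param thresholds A [detection_thresholds()].
#' @return Data frame of class `stream_log`: `kind`, `start_s`, `onset_s`,
#'   `decision_time`, `latency_s` (= decision_time - onset_s).
#' @export
stream_detect <- function(packets, profile, thresholds = detection_thresholds()) {
  if (inherits(packets, "fog_recording")) packets <- packetize(packets)
  stopifnot(inherits(packets, "packet_stream"))
  .check_profile(profile)
  st <- onset_detector(profile, thresholds,
                       sampling_rate = attr(packets, "sampling_rate"),
                       t0 = attr(packets, "t0"))
  acc <- list()
  for (p in packets) {
    for (i in seq_along(p$left)) {
      st <- .od_step(st, p$left[i], p$right[i])
      for (e in st$emitted) {
        e$decision_time <- max(e$onset_s, p$delivery_time)
        acc[[length(acc) + 1L]] <- e
      }
    }
  }
  out <- if (length(acc)) {
    do.call(rbind, lapply(acc, function(e) {
      data.frame(kind = e$kind, start_s = e$start_s, onset_s = e$onset_s,
                 decision_time = e$decision_time,
                 latency_s = e$decision_time - e$onset_s,
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(kind = character(), start_s = numeric(), onset_s = numeric(),
               decision_time = numeric(), latency_s = numeric(),
               stringsAsFactors = FALSE)
  }
  structure(out, class = c("stream_log", class(out)))
}

#' Cueing controller state
#'
#' @param modality Cueing modality metadata: `"auditory"`, `"visual"` or
#'   `"both"`.
#' @param hold_s Seconds of continuous normal gait required before cueing
#'   deactivates (default 30).
#' @return An object of class `cue_state` with fields `mode`
#'   (`idle`/`cueing`), `cueing_since`, `normal_since`, `modality`,
#'   `hold_s`, `last_t`.
#' @export
cue_state <- function(modality = c("auditory", "visual", "both"), hold_s = 30) {
  modality <- match.arg(modality)
  structure(list(mode = "idle", cueing_since = NULL, normal_since = NULL,
                 modality = modality, hold_s = hold_s, last_t = -Inf),
            class = "cue_state")
}

#' Advance the cueing controller
#'
#' Cueing activates at the first FoG flag and keeps on until the wearer's
#' usual gait has been maintained for `hold_s` seconds in a continuum
#' (default 30 s): any FoG flag during the countdown clears it.
#'
#' @param state A [cue_state()].
#' @param fog_active Logical: is FoG flagged at time `t`?
#' @param t Current time in seconds; must be non-decreasing across calls.
#' @return The updated `cue_state`.
#' @examples
#' s <- cueing_step(cue_state(), TRUE, 5)    # activates
#' s <- cueing_step(s, FALSE, 10)            # countdown starts
#' cueing_step(s, FALSE, 40)$mode            # "idle" after 30 s of normal gait
#' @export
cueing_step <- function(state, fog_active, t) {
  stopifnot(inherits(state, "cue_state"))
  if (t < state$last_t) {
    stop("sequencing error: time must be non-decreasing", call. = FALSE)
  }
  state$last_t <- t
  if (state$mode == "idle") {
    if (isTRUE(fog_active)) {
      state$mode <- "cueing"
      state$cueing_since <- t
      state$normal_since <- NULL
    }
  } else {
    if (isTRUE(fog_active)) {
      state$normal_since <- NULL
    } else {
      if (is.null(state$normal_since)) state$normal_since <- t
      if (t - state$normal_since >= state$hold_s) {
        state$mode <- "idle"
        state$cueing_since <- NULL
        state$normal_since <- NULL
      }
    }
  }
  state
}

#' @export
print.cue_state <- function(x, ...) {
  cat(sprintf("<cue_state> %s (%s)%s\n", x$mode, x$modality,
              if (x$mode == "cueing" && !is.null(x$normal_since))
                sprintf(", normal gait since t = %g s", x$normal_since) else ""))
  invisible(x)
}

#' Sensor wear-life budget
#'
#' Converts a PSU's compression-cycle fatigue rating into an expected
#' wearing life at a given daily step count (one compression per step;
#' months of 30.44 days).
#'
#' @param cycle_rating Rated compression cycles (> 0).
#' @param steps_per_day Daily steps (> 0).
#' @return An object of class `device_budget` with fields `cycle_rating`,
#'   `steps_per_day`, `wear_life_days`, `wear_life_months`.
#' @examples
#' wear_life(1e6, 8000)   # 125 days, about 4.1 months
#' @export
wear_life <- function(cycle_rating, steps_per_day) {
  if (!is.numeric(cycle_rating) || cycle_rating <= 0 ||
      !is.numeric(steps_per_day) || steps_per_day <= 0) {
    stop("parameter error: cycle_rating and steps_per_day must be > 0",
         call. = FALSE)
  }
  days <- cycle_rating / steps_per_day
  structure(list(cycle_rating = cycle_rating, steps_per_day = steps_per_day,
                 wear_life_days = days, wear_life_months = days / 30.44),
            class = "device_budget")
}

#' @export
print.device_budget <- function(x, ...) {
  cat(sprintf("<device_budget> %g cycles at %g steps/day: %g days (%.2f months)\n",
              x$cycle_rating, x$steps_per_day, x$wear_life_days,
              x$wear_life_months))
  invisible(x)
}
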