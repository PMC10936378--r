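# FoG detection: calibration, indices, offline events, online onset detector.

#' Detection thresholds
#'
#' Dimensionless multipliers turning per-user calibration baselines into
#' FoG decision thresholds. A double-support episode is flagged when its
#' duration reaches `k_ds` times the baseline double-support mean; a swing
#' is "short" when its duration is at most the baseline swing mean divided
#' by `k_sw`; `m_sw` consecutive short swings of the same foot flag a
#' shuffling event. The defaults 4.7 and 4.5 are the values trained on the
#' original 35-trial clinical dataset and ship as reference defaults.
#'
#' @param k_ds,k_sw Ratio thresholds, both > 1.
#' @param m_sw Number of consecutive short swings required (default 2).
#' @param merge_gap Detections separated by a gap smaller than this many
#'   seconds are merged into one clinical event (default 0.5, below one
#'   gait cycle).
#' @return An object of class `detection_thresholds`.
#' @export
detection_thresholds <- function(k_ds = 4.7, k_sw = 4.5, m_sw = 2,
                                 merge_gap = 0.5) {
  if (!is.numeric(k_ds) || length(k_ds) != 1L || k_ds <= 1) {
    stop("`k_ds` must be a single ratio > 1", call. = FALSE)
  }
  if (!is.numeric(k_sw) || length(k_sw) != 1L || k_sw <= 1) {
    stop("`k_sw` must be a single ratio > 1", call. = FALSE)
  }
  if (!is.numeric(m_sw) || length(m_sw) != 1L || m_sw < 1) {
    stop("`m_sw` must be a count >= 1", call. = FALSE)
  }
  if (!is.numeric(merge_gap) || length(merge_gap) != 1L || merge_gap < 0) {
    stop("`merge_gap` must be a non-negative duration in seconds", call. = FALSE)
  }
  structure(list(k_ds = k_ds, k_sw = k_sw, m_sw = as.integer(m_sw),
                 merge_gap = merge_gap),
            class = "detection_thresholds")
}

#' @export
print.detection_thresholds <- function(x, ...) {
  cat(sprintf("<detection_thresholds> k_ds = %g, k_sw = %g, m_sw = %d, merge_gap = %g s\n",
              x$k_ds, x$k_sw, x$m_sw, x$merge_gap))
  invisible(x)
}

#' Calibration profile
#'
#' Per-user baseline phase durations obtained from a FoG-free calibration
#' walk (straight lines and turns): the arithmetic mean of non-truncated
#' double-support episode durations, the arithmetic mean of pooled
#' (both feet) non-truncated swing durations, and its reciprocal (small
#' shuffling steps induce high values of the reciprocal swing peak).
#'
#' @param baseline_ds,baseline_sw Baseline means in seconds, > 0.
#' @param n_ds,n_sw Episode counts behind each mean.
#' @return An object of class `calibration_profile` with fields
#'   `baseline_ds`, `baseline_sw`, `baseline_sw_recip`, `n_ds`, `n_sw`.
#' @export
calibration_profile <- function(baseline_ds, baseline_sw, n_ds = NA_integer_,
                                n_sw = NA_integer_) {
  if (!is.numeric(baseline_ds) || baseline_ds <= 0 ||
      !is.numeric(baseline_sw) || baseline_sw <= 0) {
    stop("baselines must be positive durations in seconds", call. = FALSE)
  }
  structure(list(baseline_ds = baseline_ds, baseline_sw = baseline_sw,
                 baseline_sw_recip = 1 / baseline_sw,
                 n_ds = as.integer(n_ds), n_sw = as.integer(n_sw)),
            class = "calibration_profile")
}

#' @export
print.calibration_profile <- function(x, ...) {
  cat(sprintf(paste0("<calibration_profile> baseline_ds = %.4f s (n = %d), ",
                     "baseline_sw = %.4f s (n = %d)\n"),
              x$baseline_ds, x$n_ds, x$baseline_sw, x$n_sw))
  invisible(x)
}

#' Calibrate baselines from a FoG-free walk
#'
#' Computes the [calibration_profile()] from a recording assumed free of
#' FoG. Truncated episodes (touching a recording boundary) are excluded:
#' their durations are biased underestimates.
#'
#' @param left,right Aligned [combined_signal()]s, or a [fog_recording()]
#'   as `left`.
#' @param min_episodes Minimum number of non-truncated double-support
#'   episodes and of non-truncated swing episodes per foot (default 8).
#' @return A [calibration_profile()].
#' @examples
#' rec <- simulate_recording(sim_config(duration_s = 40, fog_rate = 0, seed = 1))
#' calibrate(rec$recording)
#' @export
calibrate <- function(left, right = NULL, min_episodes = 8) {
  if (inherits(left, "fog_recording")) {
    right <- left$right
    left <- left$left
  }
  ep <- segment_phases(left, right)
  ep <- ep[!ep$truncated, , drop = FALSE]
  ds <- ep$duration_s[ep$phase == "double_support"]
  sw_l <- ep$duration_s[ep$phase == "swing" & ep$foot == "left"]
  sw_r <- ep$duration_s[ep$phase == "swing" & ep$foot == "right"]
  deficient <- c(
    if (length(ds) < min_episodes) "double_support",
    if (length(sw_l) < min_episodes) "swing (left)",
    if (length(sw_r) < min_episodes) "swing (right)"
  )
  if (length(deficient)) {
    stop(sprintf(
      "insufficient-calibration error: too few non-truncated episodes of %s (need >= %d)",
      paste(deficient, collapse = ", "), min_episodes), call. = FALSE)
  }
  calibration_profile(baseline_ds = mean(ds),
                      baseline_sw = mean(c(sw_l, sw_r)),
                      n_ds = length(ds), n_sw = length(sw_l) + length(sw_r))
}

# Threshold arithmetic in sample units (dt = 1/Fs). A double-support run of
# `len` samples has duration len*dt >= k_ds*baseline_ds iff
# len >= ceiling(k_ds*baseline_ds/dt) (guarded against FP noise); a swing of
# `len` samples is short iff len <= floor((baseline_sw/k_sw)/dt).
.thr_ds_samples <- function(profile, thresholds, dt) {
  as.integer(ceiling(thresholds$k_ds * profile$baseline_ds / dt - 1e-9))
}
.short_sw_samples <- function(profile, thresholds, dt) {
  as.integer(floor((profile$baseline_sw / thresholds$k_sw) / dt + 1e-9))
}

.check_profile <- function(profile) {
  if (!inherits(profile, "calibration_profile")) {
    stop("calibration-required error: supply a calibration_profile (see calibrate())",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Episode-level FoG indices
#'
#' Annotates a table of phase episodes with the FoG index flags: a
#' double-support episode flags `i_ds` iff its duration is at least
#' `k_ds * baseline_ds`; a swing episode is `short` iff its duration is at
#' most `baseline_sw / k_sw` (equivalently, its reciprocal peak is at
#' least `k_sw / baseline_sw`); `i_sw` flags from the `m_sw`-th consecutive
#' short swing of the same foot onwards. Only a non-short swing of the same
#' foot resets the consecutive-short counter; truncated swings are ignored
#' (neither counted nor resetting).
#'
#' @param episodes A `phase_episodes` data frame (or any data frame with
#'   columns `phase`, `foot`, `duration_s` and optionally `truncated`,
#'   `start_s`).
#' @param profile A [calibration_profile()].
#' @param thresholds A [detection_thresholds()].
#' @return `episodes` with added columns `ratio` (duration/baseline for
#'   double support, baseline/duration for swings, NA otherwise), `short`,
#'   `i_ds`, `i_sw` and `fog` (`i_ds | i_sw`).
#' @export
fog_indices <- function(episodes, profile, thresholds = detection_thresholds()) {
  .check_profile(profile)
  ep <- as.data.frame(episodes)
  if (is.null(ep$truncated)) ep$truncated <- FALSE
  if (is.null(ep$start_s)) ep$start_s <- seq_len(nrow(ep))
  is_ds <- ep$phase == "double_support"
  is_sw <- ep$phase == "swing"
  ep$ratio <- NA_real_
  ep$ratio[is_ds] <- ep$duration_s[is_ds] / profile$baseline_ds
  ep$ratio[is_sw] <- profile$baseline_sw / ep$duration_s[is_sw]
  ep$i_ds <- is_ds & ep$duration_s >= thresholds$k_ds * profile$baseline_ds - 1e-9
  ep$short <- is_sw & !ep$truncated &
    ep$duration_s <= profile$baseline_sw / thresholds$k_sw + 1e-9
  ep$i_sw <- FALSE
  for (f in c("left", "right")) {
    idx <- which(is_sw & ep$foot == f & !ep$truncated)
    idx <- idx[order(ep$start_s[idx])]
    run <- 0L
    for (i in idx) {
      run <- if (ep$short[i]) run + 1L else 0L
      ep$i_sw[i] <- run >= thresholds$m_sw
    }
  }
  ep$fog <- ep$i_ds | ep$i_sw
  ep
}

# ---------------------------------------------------------------------------
# Offline constituent extraction (vectorized route)

# One row per raw detection before merging:
#   kind (LDDS/SSW_L/SSW_R), start_s/end_s (event interval), onset_s,
#   start_i/end_i (samples), onset_step/close_step/channel (automaton
#   bookkeeping used by the shared merge routine; see .merge_constituents).
.fog_constituents <- function(left, right, profile, thresholds) {
  .check_aligned(left, right)
  .check_profile(profile)
  n <- length(left$bits)
  dt <- 1 / left$sampling_rate
  t0 <- left$t0
  thr_ds <- .thr_ds_samples(profile, thresholds, dt)
  short_sw <- .short_sw_samples(profile, thresholds, dt)
  ep <- segment_phases(left, right)
  out <- list()

  # LDDS: double-support episodes whose sample count crossed the threshold.
  # Truncated episodes that crossed it are included: a truncated duration is
  # an underestimate, so the crossing is certain (and the online detector,
  # which cannot see the recording end, fires on them too).
  ds <- ep[ep$phase == "double_support", , drop = FALSE]
  ds <- ds[(ds$end_i - ds$start_i) >= thr_ds, , drop = FALSE]
  if (nrow(ds)) {
    out[[length(out) + 1L]] <- data.frame(
      kind = "LDDS",
      start_s = ds$start_s, end_s = ds$end_s,
      onset_s = t0 + (ds$start_i + thr_ds) * dt,
      start_i = ds$start_i, end_i = ds$end_i,
      onset_step = ds$start_i + thr_ds - 1L,   # LDDS onset is end-of-sample
      close_step = ds$end_i,
      channel = 2L,
      stringsAsFactors = FALSE
    )
  }

  # SSW per foot: maximal runs of >= m_sw consecutive short (non-truncated)
  # swings. close_step is the automaton step at which a run is provably
  # over: the first sample at which the next same-foot swing has lasted
  # longer than the short-swing bound, or the stream end.
  for (f in c("left", "right")) {
    sw_all <- ep[ep$phase == "swing" & ep$foot == f, , drop = FALSE]
    sw_all <- sw_all[order(sw_all$start_i), , drop = FALSE]
    sw <- sw_all[!sw_all$truncated, , drop = FALSE]
    if (!nrow(sw)) next
    short <- (sw$end_i - sw$start_i) <= short_sw
    r <- rle(short)
    rend <- cumsum(r$lengths)
    rstart <- rend - r$lengths + 1L
    for (j in seq_along(r$values)) {
      if (!r$values[j] || r$lengths[j] < thresholds$m_sw) next
      a <- rstart[j]; b <- rend[j]
      nxt_start <- sw_all$start_i[sw_all$start_i >= sw$end_i[b]]
      nxt <- if (length(nxt_start)) min(n, nxt_start[1L] + short_sw + 1L) else n
      out[[length(out) + 1L]] <- data.frame(
        kind = if (f == "left") "SSW_L" else "SSW_R",
        start_s = sw$start_s[a], end_s = sw$end_s[b],
        onset_s = sw$end_s[a + thresholds$m_sw - 1L],
        start_i = sw$start_i[a], end_i = sw$end_i[b],
        onset_step = sw$end_i[a + thresholds$m_sw - 1L],
        close_step = as.integer(nxt),
        channel = if (f == "left") 0L else 1L,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(kind = character(), start_s = numeric(), end_s = numeric(),
                      onset_s = numeric(), start_i = integer(), end_i = integer(),
                      onset_step = integer(), close_step = integer(),
                      channel = integer(), stringsAsFactors = FALSE))
  }
  cons <- do.call(rbind, out)
  cons[order(cons$onset_step, cons$channel, cons$start_s), , drop = FALSE]
}

# Chronological merge of constituent detections. Detections are processed in
# onset order; a new detection joins the current merged event when an earlier
# member is still open (its interval may still be running or extending) or
# when its interval start lies closer than merge_gap to the latest closed
# member end. The merged event keeps the earliest onset and that
# constituent's kind; its interval is the union span of its members.
# Ordering replicates the per-sample automaton: within one sample step the
# left foot is handled first, then the right foot, then double support
# (channel 0/1/2), and a closure precedes an emission at the same key.
.merge_constituents <- function(cons, merge_gap) {
  empty <- data.frame(kind = character(), start_s = numeric(),
                      end_s = numeric(), onset_s = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(cons)) return(list(events = empty, group = integer()))
  m <- nrow(cons)
  key <- function(step, channel, is_close) {
    step * 8 + channel * 2 + (1 - is_close)
  }
  evs <- rbind(
    data.frame(i = seq_len(m), k = key(cons$onset_step, cons$channel, 0), close = FALSE),
    data.frame(i = seq_len(m), k = key(cons$close_step, cons$channel, 1), close = TRUE)
  )
  evs <- evs[order(evs$k), , drop = FALSE]
  group <- integer(m)
  open <- 0L
  grp_end <- -Inf
  g <- 0L
  for (r in seq_len(nrow(evs))) {
    i <- evs$i[r]
    if (evs$close[r]) {
      open <- open - 1L
      grp_end <- max(grp_end, cons$end_s[i])
    } else {
      join <- open > 0L ||
        (is.finite(grp_end) && (cons$start_s[i] - grp_end) < merge_gap)
      if (!join) g <- g + 1L
      group[i] <- g
      open <- open + 1L
    }
  }
  events <- do.call(rbind, lapply(split(seq_len(m), group), function(ii) {
    lead <- ii[which.min(cons$onset_s[ii])]
    data.frame(kind = cons$kind[lead],
               start_s = min(cons$start_s[ii]),
               end_s = max(cons$end_s[ii]),
               onset_s = cons$onset_s[lead],
               stringsAsFactors = FALSE)
  }))
  events <- events[order(events$start_s), , drop = FALSE]
  rownames(events) <- NULL
  list(events = events, group = group)
}

#' Offline FoG detection
#'
#' Extracts FoG events from a complete recording: one long-double-support
#' (LDDS) detection per double-support episode whose duration reaches
#' `k_ds * baseline_ds`, and one short-swing (SSW_L / SSW_R) detection per
#' maximal run of at least `m_sw` consecutive short swings of one foot
#' (interval from the first short swing's start to the last one's end).
#' Detections separated by gaps smaller than `merge_gap` are merged into a
#' single event that keeps the earliest onset (and that detection's kind).
#' The per-sample decision satisfies `fog = i_ds | i_sw` exactly.
#'
#' @inheritParams calibrate
#' @param profile A [calibration_profile()].
#' @param thresholds A [detection_thresholds()].
#' @return An object of class `fog_detection`: list with `events` (merged
#'   event data frame of class `fog_events`: `kind`, `start_s`, `end_s`,
#'   `onset_s`), `constituents` (pre-merge detections), and `decision`
#'   (list of logical per-sample vectors `i_ds`, `i_sw`, `fog`).
#' @export
detect_fog_offline <- function(left, right = NULL, profile,
                               thresholds = detection_thresholds()) {
  if (inherits(left, "fog_recording")) {
    right <- left$right
    left <- left$left
  }
  cons <- .fog_constituents(left, right, profile, thresholds)
  merged <- .merge_constituents(cons, thresholds$merge_gap)
  events <- merged$events
  class(events) <- c("fog_events", class(events))
  n <- length(left$bits)
  i_ds <- logical(n)
  i_sw <- logical(n)
  for (r in seq_len(nrow(cons))) {
    idx <- seq.int(cons$start_i[r] + 1L, cons$end_i[r])
    if (cons$kind[r] == "LDDS") i_ds[idx] <- TRUE else i_sw[idx] <- TRUE
  }
  structure(list(events = events,
                 constituents = cons[, c("kind", "start_s", "end_s", "onset_s",
                                         "start_i", "end_i")],
                 decision = list(i_ds = i_ds, i_sw = i_sw, fog = i_ds | i_sw),
                 profile = profile, thresholds = thresholds,
                 sampling_rate = left$sampling_rate, t0 = left$t0, n = n),
            class = "fog_detection")
}

#' @export
print.fog_detection <- function(x, ...) {
  cat(sprintf("<fog_detection> %d event(s) over %.1f s (%.1f%% of samples flagged)\n",
              nrow(x$events), x$n / x$sampling_rate,
              100 * mean(x$decision$fog)))
  if (nrow(x$events)) print.data.frame(x$events, digits = 6)
  invisible(x)
}

# ---------------------------------------------------------------------------
# Online onset detector (streaming automaton)

#' Create an online FoG onset detector
#'
#' A streaming state machine fed one bilateral sample at a time (see
#' [detector_step()]). It fires a long-double-support onset at the first
#' sample where the running double-support duration reaches
#' `k_ds * baseline_ds` (once per episode), and a short-swing onset at the
#' foot strike ending the `m_sw`-th consecutive short swing of a foot.
#' Onsets falling within `merge_gap` of an earlier detection (or while an
#' earlier detection is still running) are treated as a continuation of
#' that event and not re-announced, mirroring the offline merge rule.
#'
#' @param profile A [calibration_profile()].
#' @param thresholds A [detection_thresholds()].
#' @param sampling_rate Hz.
#' @param t0 Start time in seconds.
#' @return A detector state object of class `onset_detector`.
#' @export
onset_detector <- function(profile, thresholds = detection_thresholds(),
                           sampling_rate = 32, t0 = 0) {
  .check_profile(profile)
  dt <- 1 / sampling_rate
  structure(list(
    n = 0L, dt = dt, t0 = t0,
    thr_ds = .thr_ds_samples(profile, thresholds, dt),
    short_sw = .short_sw_samples(profile, thresholds, dt),
    m_sw = thresholds$m_sw, merge_gap = thresholds$merge_gap,
    ds_len = 0L, ds_start = NA_integer_, ds_fired = FALSE,
    l_prev = NA_integer_, l_phase_start = 0L, l_initial = TRUE,
    l_swcount = 0L, l_run_start = NA_integer_, l_run_end = NA_integer_,
    l_fired = FALSE,
    r_prev = NA_integer_, r_phase_start = 0L, r_initial = TRUE,
    r_swcount = 0L, r_run_start = NA_integer_, r_run_end = NA_integer_,
    r_fired = FALSE,
    grp_end = -Inf, open = 0L,
    emitted = list()
  ), class = "onset_detector")
}

# Core transition: advance the automaton by one sample. st$emitted collects
# any onset announced at this step.
.od_step <- function(st, cl, cr) {
  st$emitted <- list()
  n <- st$n
  dt <- st$dt
  t0 <- st$t0

  announce <- function(st, kind, start_s, onset_s) {
    join <- st$open > 0L ||
      (is.finite(st$grp_end) && (start_s - st$grp_end) < st$merge_gap)
    if (!join) {
      st$emitted[[length(st$emitted) + 1L]] <-
        list(kind = kind, start_s = start_s, onset_s = onset_s,
             trigger_sample = n)
    }
    st$open <- st$open + 1L
    st
  }

  for (f in c("l", "r")) {
    b <- if (f == "l") cl else cr
    P <- function(field) paste0(f, "_", field)
    if (n == 0L) {
      st[[P("prev")]] <- b
      next
    }
    # A fired short-swing run is provably over once the current swing has
    # outlasted the short-swing bound; close it so later detections can
    # start a fresh merged event.
    if (st[[P("fired")]] && b == 0L && st[[P("prev")]] == 0L &&
        (n - st[[P("phase_start")]]) > st$short_sw) {
      st$grp_end <- max(st$grp_end, t0 + st[[P("run_end")]] * dt)
      st$open <- st$open - 1L
      st[[P("fired")]] <- FALSE
      st[[P("swcount")]] <- 0L
    }
    if (b != st[[P("prev")]]) {
      if (st[[P("prev")]] == 0L && !st[[P("initial")]]) {
        # foot strike: swing [phase_start, n) completed
        len <- n - st[[P("phase_start")]]
        if (len <= st$short_sw) {
          sc <- st[[P("swcount")]] + 1L
          st[[P("swcount")]] <- sc
          if (sc == 1L) st[[P("run_start")]] <- st[[P("phase_start")]]
          st[[P("run_end")]] <- n
          if (!st[[P("fired")]] && sc >= st$m_sw) {
            st <- announce(st, if (f == "l") "SSW_L" else "SSW_R",
                           t0 + st[[P("run_start")]] * dt, t0 + n * dt)
            st[[P("fired")]] <- TRUE
          }
        } else {
          if (st[[P("fired")]]) {
            st$grp_end <- max(st$grp_end, t0 + st[[P("run_end")]] * dt)
            st$open <- st$open - 1L
            st[[P("fired")]] <- FALSE
          }
          st[[P("swcount")]] <- 0L
        }
      }
      st[[P("initial")]] <- FALSE
      st[[P("phase_start")]] <- n
      st[[P("prev")]] <- b
    }
  }

  if (cl == 1L && cr == 1L) {
    if (st$ds_len == 0L) st$ds_start <- n
    st$ds_len <- st$ds_len + 1L
    if (!st$ds_fired && st$ds_len >= st$thr_ds) {
      st <- announce(st, "LDDS", t0 + st$ds_start * dt, t0 + (n + 1L) * dt)
      st$ds_fired <- TRUE
    }
  } else if (st$ds_len > 0L) {
    if (st$ds_fired) {
      st$grp_end <- max(st$grp_end, t0 + n * dt)
      st$open <- st$open - 1L
      st$ds_fired <- FALSE
    }
    st$ds_len <- 0L
  }

  st$n <- n + 1L
  st
}

#' Advance the online detector by one sample
#'
#' Feeds one aligned bilateral sample to an [onset_detector()]. The state
#' update is a pure function of `(state, sample)`; the previous state is
#' not modified.
#'
#' @param state An `onset_detector` state.
#' @param c_l,c_r Combined-signal bits of the left and right foot at this
#'   sample.
#' @param t Optional timestamp in seconds; must equal the expected sample
#'   time `t0 + n/Fs` (out-of-order samples raise a sequencing error).
#' @return A list with `state` (the advanced detector) and `onsets` (a data
#'   frame with zero or more rows: `kind`, `start_s`, `onset_s`).
#' @export
detector_step <- function(state, c_l, c_r, t = NULL) {
  stopifnot(inherits(state, "onset_detector"))
  if (!is.null(t)) {
    expected <- state$t0 + state$n * state$dt
    if (t < expected - 1e-9) {
      stop("sequencing error: timestamps must be non-decreasing at fixed dt",
           call. = FALSE)
    }
    if (abs(t - expected) > 1e-6) {
      stop(sprintf("sequencing error: expected sample at t = %.6f, got %.6f",
                   expected, t), call. = FALSE)
    }
  }
  st <- .od_step(state, as.integer(c_l), as.integer(c_r))
  onsets <- if (length(st$emitted)) {
    do.call(rbind, lapply(st$emitted, function(e) {
      data.frame(kind = e$kind, start_s = e$start_s, onset_s = e$onset_s,
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(kind = character(), start_s = numeric(), onset_s = numeric(),
               stringsAsFactors = FALSE)
  }
  list(state = st, onsets = onsets)
}

# Run the online automaton over full bit vectors; returns the announced
# onsets with the 0-based sample index that triggered each.
.online_scan <- function(lbits, rbits, profile, thresholds, sampling_rate,
                         t0 = 0) {
  st <- onset_detector(profile, thresholds, sampling_rate, t0)
  acc <- list()
  for (i in seq_along(lbits)) {
    st <- .od_step(st, lbits[i], rbits[i])
    if (length(st$emitted)) acc <- c(acc, st$emitted)
  }
  if (!length(acc)) {
    return(data.frame(kind = character(), start_s = numeric(),
                      onset_s = numeric(), trigger_sample = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(acc, function(e) {
    data.frame(kind = e$kind, start_s = e$start_s, onset_s = e$onset_s,
               trigger_sample = e$trigger_sample, stringsAsFactors = FALSE)
  }))
}

#' Online FoG onsets over a whole recording
#'
#' Convenience wrapper that streams a recording sample-by-sample through
#' the online detector (no packetization delay) and returns the announced
#' onsets. For any input the announced `(kind, onset_s)` set equals the
#' merged events of [detect_fog_offline()].
#'
#' @inheritParams detect_fog_offline
#' @return Data frame with columns `kind`, `start_s`, `onset_s`,
#'   `trigger_sample`.
#' @export
detect_onsets_online <- function(left, right = NULL, profile,
                                 thresholds = detection_thresholds()) {
  if (inherits(left, "fog_recording")) {
    right <- left$right
    left <- left$left
  }
  .check_aligned(left, right)
  .check_profile(profile)
  .online_scan(left$bits, right$bits, profile, thresholds,
               left$sampling_rate, left$t0)
}
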