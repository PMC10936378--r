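# Gait events and phase segmentation from combined signals.

#' Detect foot-strike and foot-off events
#'
#' Foot-strike (FS) is a 0->1 transition of the combined signal, foot-off
#' (FO) a 1->0 transition. No events are emitted at the recording
#' boundaries; a constant signal yields an empty table.
#'
#' @param combined A [combined_signal()].
#' @return A data frame of class `gait_events` with columns `foot`, `kind`
#'   (`"FS"`/`"FO"`), `sample` (0-based index of the first sample after the
#'   transition) and `time_s`.
#' @examples
#' cs <- combine_signal(c(0, 0, 1, 1, 1, 0, 0), foot = "left")
#' detect_events(cs)
#' @export
detect_events <- function(combined) {
  stopifnot(inherits(combined, "combined_signal"))
  b <- combined$bits
  dt <- 1 / combined$sampling_rate
  d <- diff(b)
  idx <- which(d != 0L)            # transition between sample idx and idx + 1
  kind <- ifelse(d[idx] > 0L, "FS", "FO")
  sample <- idx                    # 0-based index of the post-transition sample
  out <- data.frame(
    foot = rep(combined$foot, length(idx)),
    kind = kind,
    sample = as.integer(sample),
    time_s = combined$t0 + sample * dt,
    stringsAsFactors = FALSE
  )
  class(out) <- c("gait_events", class(out))
  out
}

# Maximal runs of a 0/1 vector as 0-based half-open sample intervals.
.runs <- function(bits) {
  r <- rle(as.integer(bits))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(value = r$values, start_i = starts, end_i = ends,
             stringsAsFactors = FALSE)
}

#' Segment stance, swing and double-support episodes
#'
#' Per foot, maximal runs of 1 in the combined signal are single-support
#' (stance) episodes and maximal runs of 0 are swing episodes; together
#' they tile the recording. Double-support episodes are the interval
#' intersections of left and right stance, i.e. maximal runs where both
#' combined signals are 1. Intervals are half-open `[start_s, end_s)`: an
#' episode covering samples `a..b` maps to `[a*dt, (b+1)*dt)`. Episodes
#' touching a recording boundary are flagged `truncated` and are excluded
#' from all duration statistics downstream (a partial episode's duration is
#' a biased underestimate).
#'
#' @param left,right Aligned [combined_signal()]s (equal length, rate, t0),
#'   or a single [fog_recording()] passed as `left`.
#' @return A data frame of class `phase_episodes` with columns `phase`
#'   (`single_support`/`swing`/`double_support`), `foot` (`left`/`right`/
#'   `both`), `start_s`, `end_s`, `duration_s`, `truncated`, plus 0-based
#'   sample bounds `start_i`, `end_i` (end exclusive).
#' @export
segment_phases <- function(left, right = NULL) {
  if (inherits(left, "fog_recording")) {
    right <- left$right
    left <- left$left
  }
  .check_aligned(left, right)
  n <- length(left$bits)
  dt <- 1 / left$sampling_rate
  t0 <- left$t0

  per_foot <- function(cs) {
    r <- .runs(cs$bits)
    data.frame(
      phase = ifelse(r$value == 1L, "single_support", "swing"),
      foot = cs$foot,
      start_i = r$start_i, end_i = r$end_i,
      stringsAsFactors = FALSE
    )
  }
  ds <- .runs(left$bits & right$bits)
  ds <- ds[ds$value == 1L, , drop = FALSE]
  ep <- rbind(
    per_foot(left),
    per_foot(right),
    if (nrow(ds)) data.frame(phase = "double_support", foot = "both",
                             start_i = ds$start_i, end_i = ds$end_i,
                             stringsAsFactors = FALSE)
  )
  ep$start_s <- t0 + ep$start_i * dt
  ep$end_s <- t0 + ep$end_i * dt
  ep$duration_s <- (ep$end_i - ep$start_i) * dt
  ep$truncated <- ep$start_i == 0L | ep$end_i == n
  ep <- ep[order(ep$start_s, ep$phase, ep$foot),
           c("phase", "foot", "start_s", "end_s", "duration_s", "truncated",
             "start_i", "end_i")]
  rownames(ep) <- NULL
  class(ep) <- c("phase_episodes", class(ep))
  ep
}

#' Per-sample running phase durations
#'
#' Duration accumulators with reset on condition failure:
#' `T[n] = T[n-1] + dt` while the phase condition holds at sample `n`, else
#' 0 (with `T[-1] = 0`). Conditions: single support iff the foot's combined
#' bit is 1, swing iff it is 0, double support iff both feet's bits are 1.
#' The final accumulator value inside an episode equals that episode's
#' duration.
#'
#' @inheritParams segment_phases
#' @return An object of class `running_durations`: a list with per-sample
#'   numeric series `t_ss_l`, `t_sw_l`, `t_ss_r`, `t_sw_r`, `t_ds`
#'   (seconds), plus `sampling_rate` and `t0`.
#' @export
running_durations <- function(left, right = NULL) {
  if (inherits(left, "fog_recording")) {
    right <- left$right
    left <- left$left
  }
  .check_aligned(left, right)
  dt <- 1 / left$sampling_rate
  accum <- function(cond) {
    cond <- as.logical(cond)
    r <- rle(cond)
    sequence(r$lengths) * dt * cond
  }
  structure(list(
    t_ss_l = accum(left$bits == 1L),
    t_sw_l = accum(left$bits == 0L),
    t_ss_r = accum(right$bits == 1L),
    t_sw_r = accum(right$bits == 0L),
    t_ds = accum(left$bits == 1L & right$bits == 1L),
    sampling_rate = left$sampling_rate,
    t0 = left$t0
  ), class = "running_durations")
}
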