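# Synthetic pathological-gait generator with labelled ground truth.

#' Ground-truth FoG labels
#'
#' @param start_s,end_s Episode bounds in seconds.
#' @param kind Event kinds, each one of `"LDDS"`, `"SSW_L"`, `"SSW_R"`.
#' @return A sorted, validated data frame of class `truth_labels`.
#' @export
truth_labels <- function(start_s = numeric(), end_s = numeric(),
                         kind = character()) {
  as_truth_labels(data.frame(start_s = start_s, end_s = end_s, kind = kind,
                             stringsAsFactors = FALSE))
}

#' Coerce to validated truth labels
#'
#' @param x A data frame with columns `start_s`, `end_s`, `kind`.
#' @return A `truth_labels` data frame, sorted by start, with
#'   non-overlapping well-formed intervals.
#' @export
as_truth_labels <- function(x) {
  if (inherits(x, "truth_labels")) return(x)
  x <- as.data.frame(x)
  need <- c("start_s", "end_s", "kind")
  if (!all(need %in% names(x))) {
    stop("truth labels need columns start_s, end_s, kind", call. = FALSE)
  }
  x <- x[, need, drop = FALSE]
  bad <- setdiff(unique(x$kind), c("LDDS", "SSW_L", "SSW_R"))
  if (length(bad)) {
    stop(sprintf("format error: unknown event kind '%s'", bad[1L]), call. = FALSE)
  }
  if (any(x$end_s <= x$start_s)) {
    stop("validation error: truth intervals must have end_s > start_s",
         call. = FALSE)
  }
  x <- x[order(x$start_s), , drop = FALSE]
  if (nrow(x) > 1L && any(x$start_s[-1L] < x$end_s[-nrow(x)] - 1e-9)) {
    stop("validation error: truth intervals overlap", call. = FALSE)
  }
  rownames(x) <- NULL
  structure(x, class = c("truth_labels", class(x)))
}

#' Simulation configuration
#'
#' Parameters of the synthetic gait generator. The defaults encode the
#' study conditions the detector is built for: 32 Hz binary sampling;
#' clean-gait phase durations with mean double support 0.15 s and mean
#' swing 0.45 s (8% coefficient of variation; stance is emergent, roughly
#' `ds + contralateral swing + ds`); FoG episodes arriving at 2/min whose
#' durations follow a log-normal law (sigma 0.8) truncated by rejection to
#' 0.4-31.8 s with its location calibrated so the truncated mean is 2.4 s,
#' matching the clinical cohort statistics; and a manifestation mix of 40%
#' akinesia, 40% shuffling, 20% trembling. Turns are represented
#' temporally: a fraction of double supports is widened by
#' `turn_ds_factor`. The first `clean_window_s` seconds are kept free of
#' episodes so calibration has a FoG-free window.
#'
#' @param duration_s Recording length in seconds.
#' @param sampling_rate Hz.
#' @param stance_mean,swing_mean,ds_mean Clean-gait phase means, seconds.
#' @param cv Coefficient of variation of the phase-duration draws.
#' @param fog_rate FoG episodes per minute (0 for a clean recording).
#' @param manifestation_mix Named proportions over `akinesia`, `shuffle`,
#'   `tremble`; must sum to 1.
#' @param episode_sigma Log-normal sigma of the episode-duration law.
#' @param episode_range Truncation range in seconds.
#' @param episode_mean Target truncated mean in seconds.
#' @param shuffle_swing_range Shuffling swing durations, seconds.
#' @param shuffle_stance_s Stance between shuffling swings, seconds.
#' @param tremble_freq_range Forefoot tremor frequency range, Hz.
#' @param turn_fraction Fraction of double supports widened as turns.
#' @param turn_ds_factor Widening factor for turn double supports.
#' @param clean_window_s Episode-free calibration window, seconds.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(duration_s = 180, sampling_rate = 32,
                       stance_mean = 0.65, swing_mean = 0.45, ds_mean = 0.15,
                       cv = 0.08, fog_rate = 2,
                       manifestation_mix = c(akinesia = 0.4, shuffle = 0.4,
                                             tremble = 0.2),
                       episode_sigma = 0.8, episode_range = c(0.4, 31.8),
                       episode_mean = 2.4,
                       shuffle_swing_range = c(0.05, 0.12),
                       shuffle_stance_s = 0.2,
                       tremble_freq_range = c(4, 8),
                       turn_fraction = 0.1, turn_ds_factor = 1.5,
                       clean_window_s = 30, seed = 1) {
  stopifnot(duration_s > 0, sampling_rate > 0,
            stance_mean > 0, swing_mean > 0, ds_mean > 0,
            cv >= 0, fog_rate >= 0, episode_sigma >= 0,
            length(episode_range) == 2L, episode_range[1] < episode_range[2],
            episode_range[1] > 0,
            length(shuffle_swing_range) == 2L,
            shuffle_swing_range[1] < shuffle_swing_range[2],
            shuffle_stance_s > 0,
            length(tremble_freq_range) == 2L,
            tremble_freq_range[1] <= tremble_freq_range[2],
            turn_fraction >= 0, turn_fraction <= 1, turn_ds_factor >= 1,
            clean_window_s >= 0)
  if (!setequal(names(manifestation_mix), c("akinesia", "shuffle", "tremble")) ||
      abs(sum(manifestation_mix) - 1) > 1e-9 || any(manifestation_mix < 0)) {
    stop("`manifestation_mix` must be proportions over akinesia/shuffle/tremble summing to 1",
         call. = FALSE)
  }
  structure(list(
    duration_s = duration_s, sampling_rate = sampling_rate,
    stance_mean = stance_mean, swing_mean = swing_mean, ds_mean = ds_mean,
    cv = cv, fog_rate = fog_rate,
    manifestation_mix = manifestation_mix[c("akinesia", "shuffle", "tremble")],
    episode_sigma = episode_sigma, episode_range = episode_range,
    episode_mean = episode_mean,
    shuffle_swing_range = shuffle_swing_range,
    shuffle_stance_s = shuffle_stance_s,
    tremble_freq_range = tremble_freq_range,
    turn_fraction = turn_fraction, turn_ds_factor = turn_ds_factor,
    clean_window_s = clean_window_s, seed = as.integer(seed)
  ), class = "sim_config")
}

# Mean of a log-normal(mu, sigma) restricted to [a, b].
.trunc_lnorm_mean <- function(mu, sigma, a, b) {
  if (sigma < 1e-12) return(exp(mu))
  al <- (log(a) - mu) / sigma
  be <- (log(b) - mu) / sigma
  mass <- stats::pnorm(be) - stats::pnorm(al)
  if (mass < 1e-12) return(if (al > 0) a else b)   # mass piled at one bound
  exp(mu + sigma^2 / 2) *
    (stats::pnorm(be - sigma) - stats::pnorm(al - sigma)) / mass
}

#' Calibrate the episode-duration location parameter
#'
#' Solves for the log-normal location `mu` such that the mean of the
#' distribution truncated (by rejection) to `range` equals `target_mean`
#' within `tol`. Deterministic (no sampling involved).
#'
#' @param sigma Log-normal sigma (>= 0).
#' @param range Truncation range `c(low, high)` in seconds.
#' @param target_mean Desired truncated mean in seconds; must be strictly
#'   inside `range`.
#' @param tol Absolute tolerance on the achieved mean (default 1e-3 s).
#' @return The location parameter (log scale).
#' @examples
#' mu <- calibrate_episode_location(0.8, c(0.4, 31.8), 2.4)
#' @export
calibrate_episode_location <- function(sigma = 0.8, range = c(0.4, 31.8),
                                       target_mean = 2.4, tol = 1e-3) {
  a <- range[1]; b <- range[2]
  if (!(target_mean > a && target_mean < b)) {
    stop(sprintf("infeasibility error: target mean %g s outside achievable range (%g, %g)",
                 target_mean, a, b), call. = FALSE)
  }
  if (sigma < 1e-12) return(log(target_mean))
  # The truncated mean is increasing in mu and spans (a, b) as mu runs over
  # [log(a), log(b)], so this bracket always contains the root (and keeps
  # the normal-cdf mass well away from underflow).
  f <- function(mu) .trunc_lnorm_mean(mu, sigma, a, b) - target_mean
  lower <- log(a); upper <- log(b)
  for (i in 1:60) {             # widen until the root is bracketed
    if (f(lower) <= 0) break
    lower <- lower - 2 * sigma
  }
  for (i in 1:60) {
    if (f(upper) >= 0) break
    upper <- upper + 2 * sigma
  }
  if (f(lower) > 0 || f(upper) < 0) {
    stop("infeasibility error: could not match the target truncated mean",
         call. = FALSE)
  }
  root <- stats::uniroot(f, lower = lower, upper = upper, tol = 1e-12)
  mu <- root$root
  if (abs(.trunc_lnorm_mean(mu, sigma, a, b) - target_mean) > tol) {
    stop("infeasibility error: could not match the target truncated mean",
         call. = FALSE)
  }
  mu
}

#' Sample FoG episode durations
#'
#' Draws i.i.d. durations from the calibrated truncated log-normal law by
#' rejection (so the distribution has no atoms at the range bounds). Uses
#' the current RNG state; call `set.seed()` first for reproducibility.
#'
#' @param n Number of durations.
#' @param config A [sim_config()] supplying sigma, range and target mean.
#' @return Numeric vector of `n` durations in seconds.
#' @export
sample_episode_durations <- function(n, config = sim_config()) {
  mu <- calibrate_episode_location(config$episode_sigma, config$episode_range,
                                   config$episode_mean)
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rlnorm(max(n - length(out), 16L), mu, config$episode_sigma)
    out <- c(out, draw[draw >= config$episode_range[1] &
                         draw <= config$episode_range[2]])
  }
  out[seq_len(n)]
}

#' Plan FoG episodes for a recording
#'
#' Episode starts follow a Poisson process at `fog_rate` per minute;
#' candidates falling in the reserved clean calibration window (plus a
#' snapping buffer), overlapping a previously accepted episode (2 s
#' minimum gap) or running into the last 5 s of the recording are dropped.
#' Durations are i.i.d. from the calibrated truncated log-normal and
#' manifestations multinomial per the configured mix. Fully reproducible
#' from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return Data frame with columns `start_s`, `duration_s`,
#'   `manifestation` (possibly zero rows).
#' @export
plan_episodes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  empty <- data.frame(start_s = numeric(), duration_s = numeric(),
                      manifestation = character(), stringsAsFactors = FALSE)
  if (config$fog_rate <= 0) return(empty)
  rate <- config$fog_rate / 60
  starts <- numeric(0)
  t <- 0
  repeat {
    t <- t + stats::rexp(1, rate)
    if (t > config$duration_s) break
    starts <- c(starts, t)
  }
  if (!length(starts)) return(empty)
  durs <- sample_episode_durations(length(starts), config)
  mans <- sample(names(config$manifestation_mix), length(starts),
                 replace = TRUE, prob = config$manifestation_mix)
  keep <- logical(length(starts))
  prev_end <- -Inf
  for (i in seq_along(starts)) {
    ok <- starts[i] >= config$clean_window_s + 1.5 &&
      starts[i] + durs[i] <= config$duration_s - 5 &&
      starts[i] >= prev_end + 2
    if (ok) {
      keep[i] <- TRUE
      prev_end <- starts[i] + durs[i]
    }
  }
  data.frame(start_s = starts[keep], duration_s = durs[keep],
             manifestation = mans[keep], stringsAsFactors = FALSE)
}

#' Simulate a labelled bilateral insole recording
#'
#' Generates per-sensor plantar-pressure traces for both feet, binarizes
#' them through the PSU layout and returns the recording with ground-truth
#' labels. Normal gait alternates stance and swing with a double-support
#' overlap at every step; within each contact the heel loads first (bump
#' peaking at 120 kPa over the first 60% of the contact) and the forefoot
#' afterwards (80 kPa over the last 60%), so every contact sample clears at
#' least one PSU threshold and the binarized stance equals the scheduled
#' stance to the sample. Injected episodes are snapped to the next
#' double-support instant: akinesia holds both feet loaded for the episode
#' duration; trembling additionally oscillates one forefoot about its
#' threshold at 4-8 Hz while the heel stays loaded (no foot clears the
#' ground, so both present as long double support); shuffling makes one
#' foot take rapid short swings (0.05-0.12 s) with 0.2 s stances while the
#' other stays loaded.
#'
#' @param config A [sim_config()].
#' @param layout A [sensor_layout()].
#' @return An object of class `fog_sim`: list with `recording` (a
#'   [fog_recording()] carrying the truth), `truth`, `pressures` (left and
#'   right sample-by-sensor kPa matrices), `plan` and `config`.
#' @examples
#' sim <- simulate_recording(sim_config(duration_s = 60, seed = 7))
#' sim$truth
#' @export
simulate_recording <- function(config = sim_config(), layout = sensor_layout()) {
  stopifnot(inherits(config, "sim_config"), inherits(layout, "sensor_layout"))
  Fs <- config$sampling_rate
  dt <- 1 / Fs
  N <- as.integer(round(config$duration_s * Fs))
  if (N < 2L) stop("config error: recording too short", call. = FALSE)
  plan <- plan_episodes(config)   # re-seeds from config$seed

  cv <- config$cv
  ds_draw <- function() {
    m <- config$ds_mean *
      (if (stats::runif(1) < config$turn_fraction) config$turn_ds_factor else 1)
    max(1L, as.integer(round(stats::rnorm(1, m, cv * m) * Fs)))
  }
  sw_draw <- function() {
    max(2L, as.integer(round(stats::rnorm(1, config$swing_mean,
                                          cv * config$swing_mean) * Fs)))
  }
  shuffle_sw_draw <- function() {
    max(1L, as.integer(round(stats::runif(1, config$shuffle_swing_range[1],
                                          config$shuffle_swing_range[2]) * Fs)))
  }

  # Per-foot contact intervals [start, end) in samples. Both feet start in
  # contact; `trailing` is the foot that lifts next. `t` is always a sample
  # at which both feet are in contact (a double-support onset).
  open <- c(L = 0L, R = 0L)
  contacts <- list(L = list(), R = list())
  close_contact <- function(f, end) {
    contacts[[f]][[length(contacts[[f]]) + 1L]] <<- c(open[[f]], end)
    open[[f]] <<- NA_integer_
  }
  other <- function(f) if (f == "L") "R" else "L"
  tremble_segs <- list()
  truth <- list()
  trailing <- "R"
  t <- 0L
  ei <- 1L
  horizon <- as.integer(round((config$ds_mean + config$swing_mean) * Fs))
  st_samp <- max(1L, as.integer(round(config$shuffle_stance_s * Fs)))

  while (t < N) {
    if (ei <= nrow(plan) &&
        as.integer(round(plan$start_s[ei] * Fs)) < t + horizon) {
      D <- max(1L, as.integer(round(plan$duration_s[ei] * Fs)))
      man <- plan$manifestation[ei]
      if (man %in% c("akinesia", "tremble")) {
        if (man == "tremble") {
          tf <- if (stats::runif(1) < 0.5) "L" else "R"
          freq <- stats::runif(1, config$tremble_freq_range[1],
                               config$tremble_freq_range[2])
          tremble_segs[[length(tremble_segs) + 1L]] <-
            list(foot = tf, start = t, end = t + D, freq = freq)
        }
        truth[[length(truth) + 1L]] <-
          data.frame(start_s = t * dt, end_s = (t + D) * dt, kind = "LDDS",
                     stringsAsFactors = FALSE)
        off <- t + D
        s <- sw_draw()
        if (off >= N) break
        close_contact(trailing, off)
        if (off + s >= N) break
        open[[trailing]] <- off + s
        t <- off + s
        trailing <- other(trailing)
      } else {
        sf <- if (stats::runif(1) < 0.5) "L" else "R"
        lead <- max(1L, as.integer(round(config$ds_mean * Fs)))
        cursor <- t + lead
        first_lift <- cursor
        nsw <- 0L
        repeat {
          s <- shuffle_sw_draw()
          if (cursor + s >= N) break
          close_contact(sf, cursor)
          open[[sf]] <- cursor + s
          cursor <- cursor + s
          nsw <- nsw + 1L
          if (nsw >= 2L && (cursor - first_lift) + st_samp + 3L > D) break
          cursor <- cursor + st_samp
        }
        if (nsw > 0L) {
          truth[[length(truth) + 1L]] <-
            data.frame(start_s = first_lift * dt, end_s = cursor * dt,
                       kind = paste0("SSW_", sf), stringsAsFactors = FALSE)
        }
        t <- cursor
        trailing <- other(sf)
        if (is.na(open[[sf]])) break
      }
      ei <- ei + 1L
      next
    }
    d <- ds_draw()
    s <- sw_draw()
    off <- t + d
    if (off >= N) break
    close_contact(trailing, off)
    if (off + s >= N) break
    open[[trailing]] <- off + s
    t <- off + s
    trailing <- other(trailing)
  }
  for (f in c("L", "R")) if (!is.na(open[[f]])) close_contact(f, N)

  render <- function(foot) {
    P <- matrix(0, nrow = N, ncol = 6L, dimnames = list(NULL, .SENSOR_IDS))
    for (ct in contacts[[foot]]) {
      a <- ct[1L]; b <- min(ct[2L], N)
      L <- b - a
      if (L <= 0L) next
      L1 <- max(1L, as.integer(ceiling(0.6 * L)))
      heel <- seq.int(a, a + L1 - 1L)
      P[heel + 1L, "S1"] <- 70 + 50 * sin(pi * (seq_len(L1) - 0.5) / L1)
      f0 <- as.integer(floor(0.4 * L))
      fore <- seq.int(a + f0, b - 1L)
      L2 <- length(fore)
      bump <- sin(pi * (seq_len(L2) - 0.5) / L2)
      P[fore + 1L, c("S2", "S3", "S6")] <- 45 + 35 * bump
      P[fore + 1L, c("S4", "S5")] <- 10 + 5 * bump
    }
    for (seg in tremble_segs) {
      if (seg$foot != foot) next
      idx <- seq.int(seg$start, min(seg$end, N) - 1L)
      tt <- idx * dt
      P[idx + 1L, "S1"] <- 100
      P[idx + 1L, c("S2", "S3", "S6")] <- 27.5 + 15 * sin(2 * pi * seg$freq * tt)
      P[idx + 1L, c("S4", "S5")] <- 10
    }
    pmax(P, 0)
  }
  P_L <- render("L")
  P_R <- render("R")
  truth_df <- if (length(truth)) as_truth_labels(do.call(rbind, truth)) else
    truth_labels()
  left <- binarize(P_L, layout, "left", sampling_rate = Fs)
  right <- binarize(P_R, layout, "right", sampling_rate = Fs)
  structure(list(
    recording = fog_recording(left, right, truth = truth_df),
    truth = truth_df,
    pressures = list(left = P_L, right = P_R),
    plan = plan, config = config
  ), class = "fog_sim")
}

#' @export
print.fog_sim <- function(x, ...) {
  cat(sprintf("<fog_sim> %.0f s @ %g Hz, %d injected episode(s), seed %d\n",
              x$config$duration_s, x$config$sampling_rate, nrow(x$truth),
              x$config$seed))
  invisible(x)
}
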