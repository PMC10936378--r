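# Calibration profile used by the constructed-detection tests below.
prof_15_45 <- calibration_profile(baseline_ds = 0.15, baseline_sw = 0.45)

test_that("calibration averages non-truncated episode durations", {
  Fs <- 20
  left <- mk_cs(c(12, 8, 6, 10, 8), first = 1, foot = "left", Fs = Fs)
  right <- mk_cs(c(10, 12, 16, 6), first = 1, foot = "right", Fs = Fs)
  # interior double supports 0.2 and 0.1 s; pooled swings 0.4, 0.5, 0.6 s
  prof <- calibrate(left, right, min_episodes = 1)
  expect_equal(prof$baseline_ds, 0.15)
  expect_equal(prof$baseline_sw, 0.5)
  expect_equal(prof$baseline_sw_recip, 2.0)
  expect_equal(prof$n_ds, 2L)
  expect_equal(prof$n_sw, 3L)
  # identical swings: the mean is the common value
  l2 <- mk_cs(c(5, 9, 5, 9, 5, 9, 5), first = 1, foot = "left", Fs = Fs)
  r2 <- mk_cs(c(20, 9, 18), first = 1, foot = "right", Fs = Fs)
  expect_equal(calibrate(l2, r2, min_episodes = 1)$baseline_sw, 0.45)
  # too few episodes names the deficient phase
  expect_error(calibrate(left, right, min_episodes = 8),
               "insufficient-calibration.*double_support")
})

test_that("FoG indices flag long double supports and consecutive short swings", {
  prof <- calibration_profile(baseline_ds = 0.15, baseline_sw = 0.5)
  ep <- data.frame(
    phase = c("double_support", "double_support", "swing", "swing", "swing"),
    foot = c("both", "both", "left", "left", "left"),
    start_s = 1:5, duration_s = c(0.70, 0.71, 0.10, 0.10, 0.5),
    truncated = FALSE)
  ix <- fog_indices(ep, prof)   # defaults k_ds 4.7, k_sw 4.5, m_sw 2
  expect_equal(ix$i_ds, c(FALSE, TRUE, FALSE, FALSE, FALSE))  # 4.7*0.15 = 0.705
  expect_equal(ix$short, c(FALSE, FALSE, TRUE, TRUE, FALSE))  # bound 0.5/4.5
  expect_equal(ix$i_sw, c(FALSE, FALSE, FALSE, TRUE, FALSE))  # flags on 2nd
  expect_equal(ix$fog, ix$i_ds | ix$i_sw)
  # episodes at exactly the baseline never flag (k > 1)
  base <- data.frame(phase = c("double_support", "swing"), foot = c("both", "left"),
                     start_s = 1:2, duration_s = c(0.15, 0.5), truncated = FALSE)
  expect_false(any(fog_indices(base, prof)$fog))
  expect_error(fog_indices(ep, NULL), "calibration-required")
})

test_that("an injected long-double-support block yields exactly one LDDS event", {
  left <- combine_signal(rep(1L, 480), foot = "left")
  cyc <- rep(c(rep(1L, 5), rep(0L, 14)), 8)      # normal: DS 0.156 s, swing 0.44 s
  right <- combine_signal(c(cyc, rep(1L, 64), rep(0L, 14), cyc,
                            rep(0L, 480 - 2 * length(cyc) - 78)),
                          foot = "right")
  det <- detect_fog_offline(left, right, prof_15_45)
  expect_equal(nrow(det$events), 1L)
  expect_equal(det$events$kind, "LDDS")
  blk_start <- length(cyc) / 32   # the cycle ends on a swing, so the block
  expect_equal(det$events$start_s, blk_start)   # starts the DS run exactly
  expect_equal(det$events$end_s - det$events$start_s, 64 / 32, tolerance = 1e-9)
  expect_equal(det$events$onset_s, det$events$start_s + 23 / 32)
  # a clean recording yields no events
  clean <- detect_fog_offline(left, combine_signal(rep(cyc, length.out = 480),
                                                   foot = "right"), prof_15_45)
  expect_equal(nrow(clean$events), 0L)
})

test_that("detections closer than merge_gap merge; a gap of exactly 0.5 s does not", {
  left <- combine_signal(rep(1L, 400), foot = "left")
  blk <- rep(1L, 30)                              # 0.9375 s >= 0.705 s: flagged
  mk_right <- function(gap) combine_signal(
    c(rep(0L, 20), blk, rep(0L, gap), blk, rep(0L, 400 - 80 - gap)),
    foot = "right")
  near <- detect_fog_offline(left, mk_right(9), prof_15_45)   # 0.28125 s gap
  expect_equal(nrow(near$constituents), 2L)
  expect_equal(nrow(near$events), 1L)
  expect_equal(near$events$onset_s, min(near$constituents$onset_s))
  expect_equal(near$events$start_s, min(near$constituents$start_s))
  expect_equal(near$events$end_s, max(near$constituents$end_s))
  far <- detect_fog_offline(left, mk_right(16), prof_15_45)   # exactly 0.5 s
  expect_equal(nrow(far$events), 2L)
})

test_that("the per-sample decision satisfies fog = i_ds | i_sw", {
  set.seed(31)
  for (rep in 1:10) {
    rec <- rand_recording(n = 300, max_run = 20)
    det <- detect_fog_offline(rec, profile = prof_15_45)
    expect_identical(det$decision$fog, det$decision$i_ds | det$decision$i_sw)
  }
})

test_that("online LDDS onset fires ceil(k_ds*baseline_ds/dt) samples into double support", {
  left <- combine_signal(rep(1L, 320), foot = "left")
  right <- combine_signal(c(rep(0L, 50), rep(1L, 270)), foot = "right")
  on <- detect_onsets_online(left, right, prof_15_45)
  expect_equal(nrow(on), 1L)
  # ceil(4.7 * 0.15 / (1/32)) = ceil(22.56) = 23 samples = 0.71875 s
  expect_equal(on$onset_s - on$start_s, 23 / 32)
  expect_equal(on$start_s, 50 / 32)
  # a normal stream never fires
  cyc <- rep(c(rep(1L, 5), rep(0L, 14)), length.out = 320)
  none <- detect_onsets_online(left, combine_signal(cyc, foot = "right"),
                               prof_15_45)
  expect_equal(nrow(none), 0L)
})

test_that("short-swing onsets fire at the foot strike ending the m_sw-th short swing", {
  Fs <- 32
  # left: interleave short swings (3 samples <= 0.45/4.5 = 0.1 s) with stances
  # three consecutive short swings, then a long (10-sample) swing that resets
  # the counter, then nothing: intervening stances do not reset it
  left <- mk_cs(c(40, 3, 6, 3, 6, 3, 40, 10, 99), first = 1, foot = "left", Fs = Fs)
  right <- combine_signal(rep(0L, length(left$bits)), foot = "right")
  det <- detect_fog_offline(left, right, prof_15_45)
  expect_equal(det$events$kind, "SSW_L")
  expect_equal(nrow(det$events), 1L)           # one maximal run of 3 short swings
  expect_equal(det$events$start_s, 40 / 32)    # first short swing start
  expect_equal(det$events$onset_s, 52 / 32)    # FS ending the 2nd short swing
  expect_equal(det$events$end_s, 61 / 32)      # last short swing end
  on <- detect_onsets_online(left, right, prof_15_45)
  expect_equal(nrow(on), 1L)
  expect_equal(on$onset_s, det$events$onset_s)
})

test_that("streaming and offline detection produce identical event sets", {
  set.seed(32)
  for (rep in 1:60) {
    rec <- rand_recording(n = 400, min_run = 1, max_run = 14)
    prof <- calibration_profile(baseline_ds = runif(1, 0.08, 0.2),
                                baseline_sw = runif(1, 0.2, 0.5))
    thr <- detection_thresholds(k_ds = runif(1, 1.5, 5), k_sw = runif(1, 1.5, 5),
                                m_sw = sample(1:3, 1))
    off <- detect_fog_offline(rec, profile = prof, thresholds = thr)
    on <- detect_onsets_online(rec, profile = prof, thresholds = thr)
    expect_equal(nrow(on), nrow(off$events))
    if (nrow(on)) {
      expect_equal(on$kind, off$events$kind)
      expect_equal(on$onset_s, off$events$onset_s)
    }
  }
})

test_that("raising a threshold never adds detections", {
  sim <- simulate_recording(sim_config(duration_s = 120, seed = 5))
  prof <- calibrate(sim$recording$left, sim$recording$right)
  flagged <- function(k_ds, k_sw) {
    detect_fog_offline(sim$recording, profile = prof,
                       thresholds = detection_thresholds(k_ds, k_sw))$decision
  }
  ks <- seq(1.2, 6, by = 0.4)
  prev <- flagged(ks[1], ks[1])
  for (k in ks[-1]) {
    cur <- flagged(k, k)
    expect_true(all(which(cur$i_ds) %in% which(prev$i_ds)))
    expect_true(all(which(cur$i_sw) %in% which(prev$i_sw)))
    prev <- cur
  }
})

test_that("the step API is pure and rejects out-of-order timestamps", {
  st <- onset_detector(prof_15_45)
  r1 <- detector_step(st, 1, 1, t = 0)
  expect_equal(st$n, 0L)                      # input state untouched
  expect_equal(r1$state$n, 1L)
  r2 <- detector_step(r1$state, 1, 1, t = 1 / 32)
  expect_error(detector_step(r2$state, 1, 1, t = 0), "sequencing error")
  # feeding a stream step-by-step matches the batch scan
  set.seed(33)
  rec <- rand_recording(n = 200)
  st <- onset_detector(prof_15_45)
  acc <- NULL
  for (i in seq_len(200)) {
    r <- detector_step(st, rec$left$bits[i], rec$right$bits[i])
    st <- r$state
    if (nrow(r$onsets)) acc <- rbind(acc, r$onsets)
  }
  batch <- detect_onsets_online(rec, profile = prof_15_45)
  expect_equal(if (is.null(acc)) 0L else nrow(acc), nrow(batch))
  if (!is.null(acc)) expect_equal(acc$onset_s, batch$onset_s)
})
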