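test_that("the episode-duration location matches a quadrature oracle", {
  mu <- calibrate_episode_location(0.8, c(0.4, 31.8), 2.4)
  # independent oracle: numerically integrate the truncated mean
  num <- stats::integrate(function(x) x * stats::dlnorm(x, mu, 0.8), 0.4, 31.8,
                          rel.tol = 1e-10)$value
  den <- stats::integrate(function(x) stats::dlnorm(x, mu, 0.8), 0.4, 31.8,
                          rel.tol = 1e-10)$value
  expect_equal(num / den, 2.4, tolerance = 1e-3)
  expect_equal(mu, log(2.4) - 0.32, tolerance = 0.1)
  # degenerate distribution: location collapses to log(target)
  expect_equal(calibrate_episode_location(1e-14, c(0.4, 31.8), 2.4), log(2.4))
  # a target beyond the range cap is infeasible
  expect_error(calibrate_episode_location(0.8, c(0.4, 31.8), 50),
               "infeasibility")
})

test_that("sampled episode durations match the cohort statistics", {
  cfg <- sim_config()
  set.seed(1)
  d <- sample_episode_durations(1500, cfg)
  expect_true(all(d >= 0.4 & d <= 31.8))     # range respected by construction
  expect_equal(mean(d), 2.4, tolerance = 0.1 / 2.4)
})

test_that("episode planning is reproducible and respects its margins", {
  cfg <- sim_config(duration_s = 300, seed = 9)
  p1 <- plan_episodes(cfg)
  p2 <- plan_episodes(cfg)
  expect_identical(p1, p2)
  expect_true(all(p1$start_s >= 31.5))
  expect_true(all(p1$start_s + p1$duration_s <= 295))
  if (nrow(p1) > 1) {
    expect_true(all(p1$start_s[-1] >= (p1$start_s + p1$duration_s)[-nrow(p1)] + 2))
  }
  expect_equal(nrow(plan_episodes(sim_config(fog_rate = 0))), 0L)
})

test_that("a clean recording alternates stance and swing with no labels", {
  sim <- simulate_recording(sim_config(duration_s = 60, fog_rate = 0, seed = 4))
  expect_equal(nrow(sim$truth), 0L)
  ep <- segment_phases(sim$recording)
  for (f in c("left", "right")) {
    e <- ep[ep$foot == f, ]
    expect_true(all(e$phase[-1] != e$phase[-nrow(e)]))   # strict alternation
    interior <- e[!e$truncated, ]
    expect_true(all(interior$duration_s > 0))
  }
  # a clean window calibrates without error and near the configured means
  prof <- calibrate(sim$recording)
  expect_equal(prof$baseline_sw, 0.45, tolerance = 0.1)
  expect_gt(prof$baseline_ds, 0.1)
  expect_lt(prof$baseline_ds, 0.25)
})

test_that("simulation is bit-identical under a fixed seed", {
  a <- simulate_recording(sim_config(duration_s = 90, seed = 12))
  b <- simulate_recording(sim_config(duration_s = 90, seed = 12))
  expect_identical(a$recording$left$bits, b$recording$left$bits)
  expect_identical(a$recording$right$bits, b$recording$right$bits)
  expect_identical(a$truth, b$truth)
  c <- simulate_recording(sim_config(duration_s = 90, seed = 13))
  expect_false(identical(a$recording$left$bits, c$recording$left$bits))
})

test_that("injected episodes reappear in the segmentation as designed", {
  found_ldds <- 0L; found_ssw <- 0L
  for (seed in 1:8) {
    sim <- simulate_recording(sim_config(duration_s = 120, fog_rate = 3,
                                         seed = seed))
    ep <- segment_phases(sim$recording)
    ds <- ep[ep$phase == "double_support", ]
    for (i in seq_len(nrow(sim$truth))) {
      tr <- sim$truth[i, ]
      if (tr$kind == "LDDS") {
        found_ldds <- found_ldds + 1L
        # exactly one double-support episode covering the truth interval,
        # with matching duration (to one sample)
        hit <- ds[ds$start_s <= tr$start_s + 1e-9 & ds$end_s >= tr$end_s - 1e-9, ]
        expect_equal(nrow(hit), 1L)
        expect_equal(hit$duration_s, tr$end_s - tr$start_s, tolerance = 1 / 32)
        expect_gte(hit$duration_s, 0.4 - 1 / 32)
      } else {
        found_ssw <- found_ssw + 1L
        f <- if (tr$kind == "SSW_L") "left" else "right"
        sw <- ep[ep$phase == "swing" & ep$foot == f &
                   ep$start_s >= tr$start_s - 1e-9 & ep$end_s <= tr$end_s + 1e-9, ]
        expect_gte(nrow(sw), 2L)                 # at least m_sw short swings
        expect_true(all(sw$duration_s <= 0.13))  # all shuffling-short
      }
    }
    # the first 30 s are clean by construction
    if (nrow(sim$truth)) expect_gt(min(sim$truth$start_s), 30)
  }
  expect_gt(found_ldds, 0L)   # both manifestation families exercised
  expect_gt(found_ssw, 0L)
})

test_that("clean and freezing gait are separable by construction", {
  sim <- simulate_recording(sim_config(duration_s = 180, seed = 2))
  prof <- calibrate(gaitfog:::.crop_signal(sim$recording$left, 30),
                    gaitfog:::.crop_signal(sim$recording$right, 30))
  inst <- build_instances(segment_phases(sim$recording), sim$truth, prof)
  if (any(inst$label == "fog") && any(inst$label == "normal")) {
    for (kind in unique(inst$kind[inst$label == "fog"])) {
      sub <- inst[inst$kind == kind, ]
      if (length(unique(sub$label)) < 2) next
      fit <- train_thresholds(sub)
      expect_equal(fit$sensitivity + fit$specificity, 2)
    }
  }
  # pressures clear the PSU thresholds as designed: peaks at 120/80 kPa
  expect_equal(max(sim$pressures$left[, "S1"]), 120, tolerance = 0.02)
  expect_lte(max(sim$pressures$left[, "S2"]), 80)
  # S4/S5 never reach their 20 kPa threshold outside tremor overrides
  expect_lt(max(sim$pressures$left[, "S4"]), 20)
})
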