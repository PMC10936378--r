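prof <- calibration_profile(baseline_ds = 0.15, baseline_sw = 0.5)

test_that("instances bridge episodes to labelled ratios", {
  ep <- data.frame(
    phase = c("double_support", "double_support"), foot = "both",
    start_s = c(1, 10), end_s = c(3, 10.45), duration_s = c(2, 0.45),
    truncated = FALSE, start_i = 0L, end_i = 0L)
  tr <- truth_labels(0.5, 4, "LDDS")
  inst <- build_instances(ep, tr, prof)
  expect_equal(inst$label, c("fog", "normal"))
  expect_equal(inst$ratio, c(2 / 0.15, 3.0))       # 0.45 / 0.15 = 3
  # no truth intervals: everything normal
  inst0 <- build_instances(ep, truth_labels(), prof)
  expect_true(all(inst0$label == "normal"))
  expect_equal(nrow(build_instances(ep[0, ], truth_labels(), prof)), 0L)
})

test_that("swing runs are per foot, grouped by label, scored by their shortest swing", {
  ep <- data.frame(
    phase = rep("swing", 5),
    foot = c("left", "left", "left", "right", "left"),
    start_s = c(1, 2, 10, 10.2, 12), end_s = c(1.4, 2.1, 10.1, 10.6, 12.5),
    duration_s = c(0.4, 0.1, 0.1, 0.4, 0.5), truncated = FALSE)
  tr <- truth_labels(c(1.9, 9.9), c(2.2, 10.15), c("SSW_L", "SSW_L"))
  inst <- build_instances(ep, tr, prof)
  l <- inst[inst$foot == "left", ]
  # left: normal run {0.4}, fog run {0.1, 0.1}, normal run {0.5}
  expect_equal(l$label, c("normal", "fog", "normal"))
  expect_equal(l$ratio, c(0.5 / 0.4, 0.5 / 0.1, 0.5 / 0.5))
  # the right swing overlaps an SSW_L interval but is labelled by SSW_R only
  expect_equal(inst$label[inst$foot == "right"], "normal")
})

test_that("the fuzzy zone spans min-fog to max-normal, sorted", {
  inst <- data.frame(ratio = c(1, 1.5, 2, 6, 7),
                     label = c("normal", "normal", "normal", "fog", "fog"))
  z <- compute_fuzzy_zone(inst)
  expect_equal(c(z$low, z$high), c(2, 6))
  z2 <- compute_fuzzy_zone(data.frame(ratio = c(1, 2, 3, 2.5, 4, 5),
                                      label = rep(c("normal", "fog"), each = 3)))
  expect_equal(c(z2$low, z2$high), c(2.5, 3.0))
  expect_error(compute_fuzzy_zone(data.frame(ratio = 1:3, label = "fog")),
               "degenerate-zone")
})

test_that("threshold training maximises sensitivity + specificity on the grid", {
  inst <- data.frame(ratio = c(1, 2, 3, 2.5, 4, 5),
                     label = rep(c("normal", "fog"), each = 3))
  fit <- train_thresholds(inst)
  expect_equal(fit$k, 2.5)
  expect_equal(fit$sensitivity, 1)
  expect_equal(fit$specificity, 2 / 3)
  # separable classes: whole interior scores 2; midpoint tie-break, exact
  # half rounding to the lower grid point
  sep <- data.frame(ratio = c(1, 1.5, 2, 6, 7),
                    label = c("normal", "normal", "normal", "fog", "fog"))
  fit2 <- train_thresholds(sep)
  expect_equal(fit2$k, 4.0)
  expect_equal(fit2$sensitivity + fit2$specificity, 2)
  expect_error(train_thresholds(data.frame(ratio = 1:3, label = "fog")),
               "degenerate-zone")
})

test_that("training agrees with an exhaustive grid oracle on random instance sets", {
  set.seed(41)
  for (rep in 1:40) {
    n <- sample(4:50, 1)
    inst <- data.frame(
      ratio = round(runif(n, 0.5, 8), 2),
      label = sample(c("fog", "normal"), n, replace = TRUE))
    if (length(unique(inst$label)) < 2) next
    fit <- train_thresholds(inst)
    # independent oracle: score every grid candidate from scratch, in exact
    # integer hundredths (ratios are 2-decimal numbers, the grid step is 0.1)
    rh <- as.integer(round(100 * inst$ratio))
    fog_h <- rh[inst$label == "fog"]
    nor_h <- rh[inst$label == "normal"]
    lo_h <- min(min(fog_h), max(nor_h))
    hi_h <- max(min(fog_h), max(nor_h))
    grid_h <- seq.int(lo_h, hi_h, by = 10L)
    oracle <- vapply(grid_h, function(k) {
      mean(fog_h >= k) + mean(nor_h < k)
    }, numeric(1))
    expect_equal(fit$sensitivity + fit$specificity, max(oracle),
                 tolerance = 1e-9)
  }
})

test_that("trained thresholds separate well-separated synthetic instances", {
  set.seed(42)
  inst <- rbind(
    data.frame(kind = "ds_episode", ratio = runif(40, 0.6, 2), label = "normal"),
    data.frame(kind = "ds_episode", ratio = runif(10, 6, 9), label = "fog"),
    data.frame(kind = "swing_run", ratio = runif(40, 0.7, 2), label = "normal"),
    data.frame(kind = "swing_run", ratio = runif(10, 6, 9), label = "fog"))
  thr <- train_detection_thresholds(inst)
  for (fit in list(attr(thr, "fit_ds"), attr(thr, "fit_sw"))) {
    expect_gt(fit$k, 2)
    expect_lte(fit$k, 6)
    expect_equal(fit$sensitivity + fit$specificity, 2)
  }
})

test_that("detection accounting reproduces the clinical worked example", {
  acc <- detection_accounting(n_pred = 662, n_true = 623, n_matched = 623)
  expect_equal(round(acc$correct_pct, 1), 94.1)
  expect_equal(round(acc$over_pct, 1), 5.9)
  expect_equal(acc$under_pct, 0)
  expect_equal(acc$correct_pct + acc$over_pct, 100)
  set.seed(43)
  for (rep in 1:20) {
    np <- sample(1:50, 1); nm <- sample(0:np, 1); nt <- nm + sample(0:10, 1)
    a <- detection_accounting(np, nt, nm)
    expect_equal(a$correct_pct + a$over_pct, 100)
  }
  expect_error(detection_accounting(5, 3, 4), "n_matched")
})

test_that("event evaluation matches greedily one-to-one with tolerance", {
  tr <- truth_labels(c(1, 5, 9), c(2, 6, 10), c("LDDS", "LDDS", "SSW_L"))
  perfect <- data.frame(kind = tr$kind, start_s = tr$start_s, end_s = tr$end_s,
                        onset_s = tr$start_s)
  inst <- data.frame(kind = "ds_episode", ratio = c(1, 1.2),
                     label = "normal")
  ev <- evaluate_events(perfect, tr, instances = inst)
  expect_equal(ev$metrics$sensitivity, 1)
  expect_equal(ev$metrics$specificity, 1)
  expect_equal(ev$metrics$accuracy, 1)
  expect_equal(ev$accounting$correct_pct, 100)
  expect_equal(ev$accounting$over_pct, 0)

  # one extra prediction overlapping no truth: fp = 1, fn = 0
  extra <- rbind(perfect, data.frame(kind = "LDDS", start_s = 20, end_s = 21,
                                     onset_s = 20))
  ev2 <- evaluate_events(extra, tr)
  expect_equal(ev2$metrics$fp, 1)
  expect_equal(ev2$metrics$fn, 0)

  # tolerance expands the truth: a prediction 0.4 s after the truth end matches
  near <- data.frame(kind = "LDDS", start_s = 2.4, end_s = 2.6, onset_s = 2.4)
  expect_equal(evaluate_events(near, tr[1, ], tol = 0.5)$metrics$tp, 1)
  expect_equal(evaluate_events(near, tr[1, ], tol = 0.1)$metrics$tp, 0)
  expect_error(evaluate_events(near, tr, tol = -1), "parameter error")
})

test_that("latency statistics summarise onset minus truth start per kind", {
  tr <- truth_labels(c(1, 5), c(3, 7), c("LDDS", "LDDS"))
  pred <- data.frame(kind = "LDDS", start_s = c(1, 5), end_s = c(3, 7),
                     onset_s = c(1.2, 5.4))
  ls <- latency_stats(pred, tr)
  expect_equal(ls$mean_s, 0.3)
  expect_equal(ls$min_s, 0.2)
  expect_equal(ls$max_s, 0.4)
  # a single matched pair collapses mean = min = max
  one <- latency_stats(pred[1, ], tr[1, ])
  expect_equal(unlist(one[c("mean_s", "min_s", "max_s")]),
               c(mean_s = 0.2, min_s = 0.2, max_s = 0.2))
  # onsets at truth starts give zero latency
  zero <- latency_stats(data.frame(kind = "LDDS", start_s = 1, end_s = 3,
                                   onset_s = 1), tr[1, ])
  expect_equal(zero$mean_s, 0)
  # no matches: empty summary marker
  none <- latency_stats(data.frame(kind = "LDDS", start_s = 50, end_s = 51,
                                   onset_s = 50), tr)
  expect_equal(nrow(none), 0L)
})
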