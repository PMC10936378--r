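# Fuzzy-zone threshold training and event-level evaluation.

.overlaps <- function(a_start, a_end, b_start, b_end) {
  a_start < b_end & a_end > b_start
}

#' Build labelled training instances
#'
#' Bridges phase segmentation to threshold training: every non-truncated
#' double-support episode becomes one `ds_episode` instance with ratio
#' `duration / baseline_ds`, and every maximal run of consecutive
#' same-foot, same-label swings becomes one `swing_run` instance with
#' ratio `baseline_sw / min(swing duration in the run)` (the run's largest
#' reciprocal swing peak). Labels are kind-matched against the ground
#' truth: a `ds_episode` is `fog` iff it overlaps an `LDDS` truth interval,
#' and a swing run of foot *f* iff it overlaps an `SSW_f` truth interval
#' (the long-double-support and short-swing indices respond to different
#' FoG manifestations and are trained independently).
#'
#' @param episodes A `phase_episodes` data frame from [segment_phases()].
#' @param truth A [truth_labels()] table (possibly empty: everything is
#'   then labelled `normal`).
#' @param profile A [calibration_profile()].
#' @return Data frame of class `fog_instances`: `kind` (`ds_episode` /
#'   `swing_run`), `foot`, `start_s`, `end_s`, `ratio`, `label`
#'   (`fog`/`normal`).
#' @export
build_instances <- function(episodes, truth, profile) {
  .check_profile(profile)
  truth <- as_truth_labels(truth)
  ep <- as.data.frame(episodes)
  out <- list()
  empty <- data.frame(kind = character(), foot = character(),
                      start_s = numeric(), end_s = numeric(),
                      ratio = numeric(), label = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(ep)) return(structure(empty, class = c("fog_instances", class(empty))))

  lab_overlap <- function(starts, ends, kinds_wanted) {
    tr <- truth[truth$kind %in% kinds_wanted, , drop = FALSE]
    if (!nrow(tr)) return(rep(FALSE, length(starts)))
    vapply(seq_along(starts), function(i) {
      any(.overlaps(starts[i], ends[i], tr$start_s, tr$end_s))
    }, logical(1))
  }

  ds <- ep[ep$phase == "double_support" & !ep$truncated, , drop = FALSE]
  if (nrow(ds)) {
    out[[length(out) + 1L]] <- data.frame(
      kind = "ds_episode", foot = "both",
      start_s = ds$start_s, end_s = ds$end_s,
      ratio = ds$duration_s / profile$baseline_ds,
      label = ifelse(lab_overlap(ds$start_s, ds$end_s, "LDDS"), "fog", "normal"),
      stringsAsFactors = FALSE
    )
  }
  for (f in c("left", "right")) {
    sw <- ep[ep$phase == "swing" & ep$foot == f & !ep$truncated, , drop = FALSE]
    sw <- sw[order(sw$start_s), , drop = FALSE]
    if (!nrow(sw)) next
    kind_f <- if (f == "left") "SSW_L" else "SSW_R"
    fog <- lab_overlap(sw$start_s, sw$end_s, kind_f)
    r <- rle(fog)
    rend <- cumsum(r$lengths)
    rstart <- rend - r$lengths + 1L
    out[[length(out) + 1L]] <- do.call(rbind, lapply(seq_along(r$values), function(j) {
      ii <- seq.int(rstart[j], rend[j])
      data.frame(kind = "swing_run", foot = f,
                 start_s = sw$start_s[ii[1L]], end_s = sw$end_s[ii[length(ii)]],
                 ratio = profile$baseline_sw / min(sw$duration_s[ii]),
                 label = if (r$values[j]) "fog" else "normal",
                 stringsAsFactors = FALSE)
    }))
  }
  inst <- if (length(out)) do.call(rbind, out) else empty
  inst <- inst[order(inst$start_s, inst$kind), , drop = FALSE]
  rownames(inst) <- NULL
  structure(inst, class = c("fog_instances", class(inst)))
}

#' Fuzzy zone of a labelled instance set
#'
#' The fuzzy zone is the ratio interval between the minimum value observed
#' when FoG happens (low boundary) and the maximum value observed during
#' normal gait (high boundary), stored sorted so that `low <= high` even
#' when the classes overlap.
#'
#' @param instances A `fog_instances` data frame (or any data frame with
#'   `ratio` and `label` columns).
#' @return An object of class `fuzzy_zone`: list with `low` and `high`.
#' @export
compute_fuzzy_zone <- function(instances) {
  fog <- instances$ratio[instances$label == "fog"]
  normal <- instances$ratio[instances$label == "normal"]
  if (!length(fog) || !length(normal)) {
    stop("degenerate-zone error: need at least one fog and one normal instance",
         call. = FALSE)
  }
  b <- sort(c(min(fog), max(normal)))
  structure(list(low = b[1L], high = b[2L]), class = "fuzzy_zone")
}

#' Train a ratio threshold by maximising sensitivity + specificity
#'
#' Evaluates every candidate threshold on the grid
#' `{low, low + step, ..., high}` spanning the fuzzy zone, classifying an
#' instance as FoG iff `ratio >= k` (the same inclusive comparison the
#' detector uses), and returns the grid point maximising
#' sensitivity + specificity. Ties are broken by taking the midpoint of the
#' maximal-scoring contiguous grid interval, rounding to the lower grid
#' point on an exact half. Sensitivity is non-increasing and specificity
#' non-decreasing in `k`; this is asserted during training.
#'
#' @param instances A labelled instance table with `ratio` and `label`.
#' @param grid_step Grid resolution on the ratio axis (default 0.1, the
#'   precision of the published 4.7 / 4.5 defaults).
#' @return An object of class `threshold_fit`: list with `k`,
#'   `sensitivity`, `specificity` (at `k`), `zone`, `grid`, `score`.
#' @examples
#' inst <- data.frame(ratio = c(1, 2, 3, 2.5, 4, 5),
#'                    label = rep(c("normal", "fog"), each = 3))
#' train_thresholds(inst)$k
#' @export
train_thresholds <- function(instances, grid_step = 0.1) {
  if (!is.numeric(grid_step) || grid_step <= 0) {
    stop("`grid_step` must be a positive ratio increment", call. = FALSE)
  }
  zone <- compute_fuzzy_zone(instances)
  fog <- instances$ratio[instances$label == "fog"]
  normal <- instances$ratio[instances$label == "normal"]
  npts <- as.integer(floor((zone$high - zone$low) / grid_step + 1e-9)) + 1L
  grid <- zone$low + grid_step * (seq_len(npts) - 1L)
  sens <- vapply(grid, function(k) mean(fog >= k - 1e-12), numeric(1))
  spec <- vapply(grid, function(k) mean(normal < k - 1e-12), numeric(1))
  if (is.unsorted(-sens) || is.unsorted(spec)) {
    stop("internal error: sensitivity/specificity not monotone over the grid")
  }
  score <- sens + spec
  best <- max(score)
  is_best <- abs(score - best) < 1e-12
  r <- rle(is_best)
  rend <- cumsum(r$lengths)
  rstart <- rend - r$lengths + 1L
  cand <- which(r$values)
  j <- cand[which.max(r$lengths[cand])]          # longest max-scoring run
  pick <- as.integer(floor((rstart[j] + rend[j]) / 2))
  structure(list(k = grid[pick], sensitivity = sens[pick],
                 specificity = spec[pick], zone = zone,
                 grid = grid, score = score),
            class = "threshold_fit")
}

#' @export
print.threshold_fit <- function(x, ...) {
  cat(sprintf("<threshold_fit> k = %g (zone [%g, %g]); sens = %.3f, spec = %.3f\n",
              x$k, x$zone$low, x$zone$high, x$sensitivity, x$specificity))
  invisible(x)
}

#' Train both detection thresholds from labelled instances
#'
#' Fits `k_ds` on the `ds_episode` instances and `k_sw` on the `swing_run`
#' instances independently (the two indices respond to different FoG
#' manifestations).
#'
#' @param instances A `fog_instances` table containing both kinds.
#' @param grid_step Grid resolution, see [train_thresholds()].
#' @param m_sw,merge_gap Passed through to [detection_thresholds()].
#' @return A [detection_thresholds()] object; the per-kind fits are
#'   attached as attributes `fit_ds` and `fit_sw`.
#' @export
train_detection_thresholds <- function(instances, grid_step = 0.1, m_sw = 2,
                                       merge_gap = 0.5) {
  fit_ds <- train_thresholds(instances[instances$kind == "ds_episode", , drop = FALSE],
                             grid_step)
  fit_sw <- train_thresholds(instances[instances$kind == "swing_run", , drop = FALSE],
                             grid_step)
  thr <- detection_thresholds(k_ds = fit_ds$k, k_sw = fit_sw$k,
                              m_sw = m_sw, merge_gap = merge_gap)
  attr(thr, "fit_ds") <- fit_ds
  attr(thr, "fit_sw") <- fit_sw
  thr
}

#' Correct / over / under detection accounting
#'
#' Event-count bookkeeping in the style of clinical reporting: with
#' `n_pred` triggered detections, `n_true` human-verified events and
#' `n_matched` one-to-one matches, the correct-detection percentage is
#' `100 * n_matched / n_pred`, over-detection is its complement, and
#' under-detection is the percentage of true events left unmatched.
#'
#' @param n_pred,n_true,n_matched Event counts; `n_matched` must not
#'   exceed either total.
#' @return An object of class `detection_accounting` with fields `n_pred`,
#'   `n_true`, `n_matched`, `correct_pct`, `over_pct`, `under_pct`.
#' @examples
#' detection_accounting(662, 623, 623)   # 94.1% correct, 5.9% over, 0% under
#' @export
detection_accounting <- function(n_pred, n_true, n_matched) {
  if (n_matched > n_pred || n_matched > n_true || any(c(n_pred, n_true, n_matched) < 0)) {
    stop("counts must satisfy 0 <= n_matched <= min(n_pred, n_true)", call. = FALSE)
  }
  structure(list(
    n_pred = n_pred, n_true = n_true, n_matched = n_matched,
    correct_pct = if (n_pred > 0) 100 * n_matched / n_pred else NA_real_,
    over_pct = if (n_pred > 0) 100 * (n_pred - n_matched) / n_pred else NA_real_,
    under_pct = if (n_true > 0) 100 * (n_true - n_matched) / n_true else NA_real_
  ), class = "detection_accounting")
}

#' @export
print.detection_accounting <- function(x, ...) {
  cat(sprintf(paste0("<detection_accounting> %d predicted / %d true / %d matched: ",
                     "%.1f%% correct, %.1f%% over, %.1f%% under\n"),
              x$n_pred, x$n_true, x$n_matched,
              x$correct_pct, x$over_pct, x$under_pct))
  invisible(x)
}

# Greedy one-to-one matching in time order between predicted event
# intervals and truth intervals expanded by tol on both sides. Returns a
# data frame of matched (pred, truth) index pairs.
.match_events <- function(predicted, truth, tol) {
  if (tol < 0) stop("parameter error: `tol` must be >= 0", call. = FALSE)
  pred <- as.data.frame(predicted)
  if (is.null(pred$end_s)) pred$end_s <- pmax(pred$start_s, pred$onset_s)
  truth <- as_truth_labels(truth)
  ord_p <- order(pred$start_s)
  ord_t <- order(truth$start_s)
  used <- logical(nrow(truth))
  pairs <- list()
  for (i in ord_p) {
    hit <- which(!used[ord_t] &
                   .overlaps(pred$start_s[i], pred$end_s[i],
                             truth$start_s[ord_t] - tol,
                             truth$end_s[ord_t] + tol))
    if (length(hit)) {
      j <- ord_t[hit[1L]]
      used[j] <- TRUE
      pairs[[length(pairs) + 1L]] <- data.frame(pred = i, truth = j)
    }
  }
  if (length(pairs)) do.call(rbind, pairs) else
    data.frame(pred = integer(), truth = integer())
}

#' Evaluate detected events against ground truth
#'
#' A prediction matches a truth episode iff their intervals overlap after
#' expanding the truth interval by `tol` on both sides (absorbing
#' annotation jitter between video and sensor clocks); matching is greedy
#' one-to-one in time order. TP is the number of matched truth episodes,
#' FN the unmatched truth, FP the unmatched predictions. The negative
#' class is episode-level: TN counts normal-labelled instances not flagged
#' at the supplied thresholds (event detection has no natural "negative
#' event", so the instance table from [build_instances()] supplies it).
#'
#' @param predicted A `fog_events` data frame (columns `kind`, `start_s`,
#'   `end_s` and optionally `onset_s`).
#' @param truth A [truth_labels()] table.
#' @param tol Matching tolerance in seconds (default 0.5).
#' @param instances Optional `fog_instances` table providing the negative
#'   class; without it specificity and accuracy are `NA`.
#' @param thresholds The [detection_thresholds()] used to flag instances.
#' @return An object of class `fog_eval`: list with `metrics` (`tp`, `fp`,
#'   `tn`, `fn`, `sensitivity`, `specificity`, `accuracy`), `accounting`
#'   (a [detection_accounting()]) and `pairs` (matched index pairs).
#' @export
evaluate_events <- function(predicted, truth, tol = 0.5, instances = NULL,
                            thresholds = detection_thresholds()) {
  truth <- as_truth_labels(truth)
  pairs <- .match_events(predicted, truth, tol)
  tp <- nrow(pairs)
  fn <- nrow(truth) - tp
  fp <- nrow(as.data.frame(predicted)) - tp
  tn <- NA_integer_
  if (!is.null(instances)) {
    flagged <- .flag_instances(instances, thresholds)
    tn <- sum(instances$label == "normal" & !flagged)
  }
  sensitivity <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  specificity <- if (!is.na(tn) && tn + fp > 0) tn / (tn + fp) else NA_real_
  accuracy <- if (!is.na(tn)) (tp + tn) / (tp + fp + tn + fn) else NA_real_
  structure(list(
    metrics = list(tp = tp, fp = fp, tn = tn, fn = fn,
                   sensitivity = sensitivity, specificity = specificity,
                   accuracy = accuracy),
    accounting = detection_accounting(n_pred = tp + fp, n_true = nrow(truth),
                                      n_matched = tp),
    pairs = pairs
  ), class = "fog_eval")
}

.flag_instances <- function(instances, thresholds) {
  k <- ifelse(instances$kind == "ds_episode", thresholds$k_ds, thresholds$k_sw)
  instances$ratio >= k - 1e-12
}

#' @export
print.fog_eval <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<fog_eval> tp %d / fp %d / tn %s / fn %d\n",
              m$tp, m$fp, as.character(m$tn), m$fn))
  cat(sprintf("  sensitivity %.3f, specificity %s, accuracy %s\n",
              m$sensitivity,
              ifelse(is.na(m$specificity), "NA", sprintf("%.3f", m$specificity)),
              ifelse(is.na(m$accuracy), "NA", sprintf("%.3f", m$accuracy))))
  print(x$accounting)
  invisible(x)
}

#' Detection-latency summary
#'
#' Latency of each matched prediction, `onset_s` minus the true episode
#' start, summarised per event kind.
#'
#' @inheritParams evaluate_events
#' @return Data frame of class `latency_summary` with columns `kind`, `n`,
#'   `mean_s`, `min_s`, `max_s` (zero rows when nothing matched).
#' @export
latency_stats <- function(predicted, truth, tol = 0.5) {
  truth <- as_truth_labels(truth)
  pred <- as.data.frame(predicted)
  if (is.null(pred$onset_s)) pred$onset_s <- pred$start_s
  pairs <- .match_events(pred, truth, tol)
  if (!nrow(pairs)) {
    out <- data.frame(kind = character(), n = integer(), mean_s = numeric(),
                      min_s = numeric(), max_s = numeric(),
                      stringsAsFactors = FALSE)
    return(structure(out, class = c("latency_summary", class(out))))
  }
  lat <- pred$onset_s[pairs$pred] - truth$start_s[pairs$truth]
  kind <- pred$kind[pairs$pred]
  out <- do.call(rbind, lapply(split(lat, kind), function(v) {
    data.frame(n = length(v), mean_s = mean(v), min_s = min(v), max_s = max(v))
  }))
  out <- cbind(data.frame(kind = rownames(out), stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  structure(out, class = c("latency_summary", class(out)))
}
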