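# Binary insole data model: PSU layouts, binarization, combined signal.

.SENSOR_IDS <- c("S1", "S2", "S3", "S4", "S5", "S6")
.FEET <- c("left", "right")

#' Specification of one pressure-sensing unit (PSU)
#'
#' A PSU is a membrane switch embedded in the insole: its output is 1
#' whenever the applied plantar pressure reaches or exceeds a fixed
#' threshold, and 0 otherwise.
#'
#' @param sensor_id One of `"S1"`..`"S6"`.
#' @param site Anatomical site, one of `"heel"`, `"metatarsal"`,
#'   `"inversion"`, `"eversion"`.
#' @param threshold Switching pressure in kPa, strictly positive.
#' @return An object of class `psu_spec`.
#' @export
psu_spec <- function(sensor_id, site, threshold) {
  sensor_id <- match.arg(sensor_id, .SENSOR_IDS)
  site <- match.arg(site, c("heel", "metatarsal", "inversion", "eversion"))
  if (!is.numeric(threshold) || length(threshold) != 1L || !is.finite(threshold) ||
      threshold <= 0) {
    stop("`threshold` must be a single positive pressure in kPa", call. = FALSE)
  }
  structure(list(sensor_id = sensor_id, site = site, threshold = threshold),
            class = "psu_spec")
}

#' Sensor layout of one insole
#'
#' Exactly six PSUs per foot: S1 at the heel (highest threshold, largest
#' impact load), S2/S3/S6 at the metatarsal heads, S4/S5 detecting foot
#' inversion and eversion (lowest thresholds). Default thresholds follow
#' the clinical-trial hardware: 50 kPa at the heel, 20 kPa for S4/S5 and
#' 27.5 kPa (the mid-range of the 20-35 kPa insole versions) at the
#' metatarsal heads.
#'
#' @param specs A list of exactly 6 [psu_spec()] objects covering S1..S6,
#'   with exactly one heel sensor (S1). Defaults to the clinical layout.
#' @return An object of class `sensor_layout`: a list with `specs` (named
#'   by sensor id) and `thresholds` (named numeric vector, kPa).
#' @examples
#' sensor_layout()$thresholds
#' @export
sensor_layout <- function(specs = NULL) {
  if (is.null(specs)) {
    specs <- list(
      psu_spec("S1", "heel", 50),
      psu_spec("S2", "metatarsal", 27.5),
      psu_spec("S3", "metatarsal", 27.5),
      psu_spec("S4", "inversion", 20),
      psu_spec("S5", "eversion", 20),
      psu_spec("S6", "metatarsal", 27.5)
    )
  }
  if (!is.list(specs) || length(specs) != 6L ||
      !all(vapply(specs, inherits, logical(1), "psu_spec"))) {
    stop("`specs` must be a list of exactly 6 psu_spec objects", call. = FALSE)
  }
  ids <- vapply(specs, `[[`, character(1), "sensor_id")
  if (anyDuplicated(ids) || !setequal(ids, .SENSOR_IDS)) {
    stop("layout error: sensor ids must be S1..S6, each exactly once", call. = FALSE)
  }
  sites <- vapply(specs, `[[`, character(1), "site")
  if (sum(sites == "heel") != 1L || sites[ids == "S1"] != "heel") {
    stop("layout error: exactly one heel sensor, and it must be S1", call. = FALSE)
  }
  specs <- specs[match(.SENSOR_IDS, ids)]
  names(specs) <- .SENSOR_IDS
  thresholds <- vapply(specs, `[[`, numeric(1), "threshold")
  structure(list(specs = specs, thresholds = thresholds), class = "sensor_layout")
}

#' Binary insole stream
#'
#' Time-indexed binary frames from the six PSUs of one foot. Sample `n`
#' (0-based) corresponds to time `t0 + n / sampling_rate` seconds.
#'
#' @param bits Integer/numeric matrix with one row per sample and 6 columns
#'   (S1..S6), all values in {0, 1}.
#' @param foot `"left"` or `"right"`.
#' @param sampling_rate Sampling frequency in Hz (default 32).
#' @param t0 Time of sample 0 in seconds (default 0).
#' @return An object of class `insole_stream`.
#' @export
insole_stream <- function(bits, foot, sampling_rate = 32, t0 = 0) {
  foot <- match.arg(foot, .FEET)
  bits <- as.matrix(bits)
  if (nrow(bits) < 1L) stop("empty-input error: stream must contain >= 1 frame", call. = FALSE)
  if (ncol(bits) != 6L) stop("frames must have exactly 6 sensor bits", call. = FALSE)
  if (!all(bits %in% c(0, 1))) stop("frame values must be 0 or 1", call. = FALSE)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L || sampling_rate <= 0) {
    stop("`sampling_rate` must be a single positive Hz value", call. = FALSE)
  }
  storage.mode(bits) <- "integer"
  colnames(bits) <- .SENSOR_IDS
  structure(list(foot = foot, sampling_rate = sampling_rate,
                 bits = bits, t0 = t0),
            class = "insole_stream")
}

#' @export
print.insole_stream <- function(x, ...) {
  cat(sprintf("<insole_stream> %s foot, %d frames @ %g Hz (%.3f s)\n",
              x$foot, nrow(x$bits), x$sampling_rate,
              nrow(x$bits) / x$sampling_rate))
  invisible(x)
}

#' Binarize per-sensor pressure traces
#'
#' Applies each PSU's switching rule: the output bit is 1 iff the applied
#' pressure reaches or exceeds the sensor's threshold (boundary inclusive),
#' 0 otherwise.
#'
#' @param pressure_traces Numeric matrix (samples x 6, columns S1..S6) or a
#'   named list of 6 equal-length numeric vectors, pressures in kPa (>= 0).
#' @param layout A [sensor_layout()].
#' @param foot `"left"` or `"right"`.
#' @param sampling_rate Hz.
#' @param t0 Start time in seconds.
#' @return An [insole_stream()].
#' @examples
#' p <- matrix(0, nrow = 4, ncol = 6, dimnames = list(NULL, paste0("S", 1:6)))
#' p[, "S1"] <- c(0, 49, 50, 120)
#' binarize(p, sensor_layout(), "left")$bits[, "S1"]
#' @export
binarize <- function(pressure_traces, layout = sensor_layout(), foot,
                     sampling_rate = 32, t0 = 0) {
  stopifnot(inherits(layout, "sensor_layout"))
  if (is.list(pressure_traces) && !is.data.frame(pressure_traces)) {
    lens <- lengths(pressure_traces)
    if (length(unique(lens)) != 1L) {
      stop("length error: all 6 pressure traces must have the same length",
           call. = FALSE)
    }
    nms <- names(pressure_traces)
    if (is.null(nms) || !setequal(nms, .SENSOR_IDS)) {
      stop("layout error: traces must be named S1..S6", call. = FALSE)
    }
    pressure_traces <- do.call(cbind, pressure_traces[.SENSOR_IDS])
  }
  pressure_traces <- as.matrix(pressure_traces)
  if (ncol(pressure_traces) != 6L) {
    stop("layout error: expected 6 sensor traces", call. = FALSE)
  }
  if (!is.null(colnames(pressure_traces))) {
    if (!setequal(colnames(pressure_traces), .SENSOR_IDS)) {
      stop("layout error: unknown sensor id in trace columns", call. = FALSE)
    }
    pressure_traces <- pressure_traces[, .SENSOR_IDS, drop = FALSE]
  }
  if (any(pressure_traces < 0)) stop("pressures must be >= 0 kPa", call. = FALSE)
  thr <- matrix(layout$thresholds, nrow = nrow(pressure_traces), ncol = 6L,
                byrow = TRUE)
  bits <- (pressure_traces >= thr) * 1L
  insole_stream(bits, foot = foot, sampling_rate = sampling_rate, t0 = t0)
}

#' Combined signal of one foot
#'
#' Per-sample logical OR across the six PSU bits: the combined signal is 1
#' while the foot is loaded anywhere (single support) and 0 while it is
#' fully off the ground (swing). Foot-strike and foot-off are its 0->1 and
#' 1->0 transitions.
#'
#' @param stream An [insole_stream()], or a 0/1 vector (with `foot`,
#'   `sampling_rate`, `t0` supplied) for already-combined bits.
#' @param foot,sampling_rate,t0 Used only when `stream` is a bare vector.
#' @return An object of class `combined_signal`: list with `foot`,
#'   `sampling_rate`, `bits` (integer 0/1 vector) and `t0`.
#' @export
combine_signal <- function(stream, foot = NULL, sampling_rate = 32, t0 = 0) {
  if (inherits(stream, "insole_stream")) {
    bits <- as.integer(rowSums(stream$bits) > 0L)
    foot <- stream$foot
    sampling_rate <- stream$sampling_rate
    t0 <- stream$t0
  } else {
    bits <- as.integer(stream)
    if (length(bits) < 1L) stop("empty-input error: empty signal", call. = FALSE)
    if (!all(bits %in% c(0L, 1L))) stop("bits must be 0 or 1", call. = FALSE)
    foot <- match.arg(foot, .FEET)
  }
  structure(list(foot = foot, sampling_rate = sampling_rate,
                 bits = bits, t0 = t0),
            class = "combined_signal")
}

#' @export
print.combined_signal <- function(x, ...) {
  cat(sprintf("<combined_signal> %s foot, %d samples @ %g Hz, %.1f%% loaded\n",
              x$foot, length(x$bits), x$sampling_rate, 100 * mean(x$bits)))
  invisible(x)
}

# Shared alignment check for bilateral operations.
.check_aligned <- function(left, right) {
  stopifnot(inherits(left, "combined_signal"), inherits(right, "combined_signal"))
  if (length(left$bits) != length(right$bits)) {
    stop("alignment error: left and right signals differ in length", call. = FALSE)
  }
  if (abs(left$sampling_rate - right$sampling_rate) > 1e-9) {
    stop("alignment error: left and right sampling rates differ", call. = FALSE)
  }
  if (abs(left$t0 - right$t0) > 1e-9) {
    stop("alignment error: left and right start times differ", call. = FALSE)
  }
  invisible(TRUE)
}

#' Bilateral insole recording
#'
#' Bundles the left and right streams of one walking recording. The two
#' streams must share sampling rate, start time and length (no resampling
#' is attempted).
#'
#' @param left,right [insole_stream()] or [combined_signal()] objects for
#'   the respective feet.
#' @param truth Optional [truth_labels()] ground-truth annotation.
#' @return An object of class `fog_recording` with elements `left`,
#'   `right` (combined signals), `streams` (the original insole streams,
#'   when given) and `truth`.
#' @export
fog_recording <- function(left, right, truth = NULL) {
  streams <- NULL
  if (inherits(left, "insole_stream") && inherits(right, "insole_stream")) {
    streams <- list(left = left, right = right)
    left <- combine_signal(left)
    right <- combine_signal(right)
  }
  if (left$foot != "left" || right$foot != "right") {
    stop("`left` must be the left foot and `right` the right foot", call. = FALSE)
  }
  .check_aligned(left, right)
  if (!is.null(truth)) truth <- as_truth_labels(truth)
  structure(list(left = left, right = right, streams = streams, truth = truth),
            class = "fog_recording")
}

#' @export
print.fog_recording <- function(x, ...) {
  n <- length(x$left$bits)
  cat(sprintf("<fog_recording> %d samples @ %g Hz (%.1f s)%s\n",
              n, x$left$sampling_rate, n / x$left$sampling_rate,
              if (is.null(x$truth)) "" else
                sprintf(", %d labelled FoG episode(s)", nrow(x$truth))))
  invisible(x)
}
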