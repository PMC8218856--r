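#' Re-reference epochs to the average of the two earlobe channels
#'
#' Subtracts `(left + right) / 2` from every channel at every sample, the
#' offline linked-earlobe reference.
#'
#' @param e an [epochs()] object.
#' @param left,right earlobe channel labels.
#' @return re-referenced `epochs` (history appended).
#' @export
rereference_earlobes <- function(e, left = "A1", right = "A2") {
  for (lab in c(left, right))
    if (!lab %in% e$channels) stop("reference channel not present: ", lab)
  il <- match(left, e$channels)
  ir <- match(right, e$channels)
  ref <- (e$data[, il, , drop = FALSE] + e$data[, ir, , drop = FALSE]) / 2
  e$data <- e$data - ref[, rep(1, dim(e$data)[2]), , drop = FALSE]
  .append_history(e, "rereference_earlobes", list(left = left, right = right))
}

# Butterworth design shared by filter_epochs; returns list of b/a sections
.design_filters <- function(fs, band, notch, order, notch_width) {
  nyq <- fs / 2
  if (any(band <= 0) || any(band >= nyq))
    stop("band edges must lie strictly inside (0, ", nyq, ") Hz")
  filt <- list()
  bp <- signal::butter(order, band / nyq, type = "pass")
  filt$band <- list(b = as.numeric(bp$b), a = as.numeric(bp$a))
  if (!is.null(notch) && is.finite(notch) && notch > 0) {
    if (notch >= nyq) stop("notch frequency must be below Nyquist")
    bs <- signal::butter(order, c(notch - notch_width / 2,
                                  notch + notch_width / 2) / nyq,
                         type = "stop")
    filt$notch <- list(b = as.numeric(bs$b), a = as.numeric(bs$a))
  }
  filt
}

#' Zero-phase band-pass and notch filtering of epochs
#'
#' Applies a second-order Butterworth band-pass (default 0.01-30 Hz) and a
#' second-order band-stop notch (default 50 Hz, 2 Hz wide) to every channel
#' of every trial. Filtering is forward-backward (zero phase) with
#' odd-reflection padding, so component latencies are not distorted.
#'
#' @param e an [epochs()] object.
#' @param band Hz pair of band-pass edges.
#' @param notch notch centre frequency in Hz, or NULL to skip.
#' @param order Butterworth order of each stage.
#' @param notch_width width of the band-stop in Hz.
#' @return filtered `epochs` (history appended).
#' @export
filter_epochs <- function(e, band = c(0.01, 30), notch = 50, order = 2,
                          notch_width = 2) {
  filt <- .design_filters(e$fs, band, notch, order, notch_width)
  d <- dim(e$data)
  x <- e$data
  padlen <- min(d[3] - 1L, 250L)
  if (!is.null(filt$notch))
    x <- array(filtfilt_arr_cpp(x, d, filt$notch$b, filt$notch$a, padlen), d)
  x <- array(filtfilt_arr_cpp(x, d, filt$band$b, filt$band$a, padlen), d)
  e$data <- x
  .append_history(e, "filter_epochs",
                  list(band = band, notch = notch, order = order))
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean over the pre-stimulus window.
#'
#' @param e an [epochs()] object.
#' @param window ms pair (inclusive) to average; default the pre-stimulus
#'   period -200..0 ms.
#' @return baseline-corrected `epochs` (history appended).
#' @export
baseline_correct <- function(e, window = c(-200, 0)) {
  idx <- .window_idx(e, window)
  bl <- rowMeans(e$data[, , idx, drop = FALSE], dims = 2)
  e$data <- e$data - array(bl, dim(e$data))
  .append_history(e, "baseline_correct", list(window = window))
}

#' Artefact rejection thresholds
#'
#' @param max_step_uv maximum permitted voltage step per sampling point.
#' @param max_range_uv maximum permitted absolute difference between two
#'   values in the segment.
#' @param min_activity_uv lowest permitted activity (peak-to-peak) within
#'   any 100-ms interval.
#' @param activity_window_ms length of the sliding activity interval.
#' @return a `rejection_rules` list.
#' @export
rejection_rules <- function(max_step_uv = 50, max_range_uv = 200,
                            min_activity_uv = 0.5, activity_window_ms = 100) {
  stopifnot(max_step_uv > 0, max_range_uv > 0, min_activity_uv > 0,
            activity_window_ms > 0)
  structure(list(max_step_uv = max_step_uv, max_range_uv = max_range_uv,
                 min_activity_uv = min_activity_uv,
                 activity_window_ms = activity_window_ms),
            class = "rejection_rules")
}

#' Threshold-based artefact rejection
#'
#' A trial is rejected if, on any channel, (a) any one-sample voltage step
#' exceeds `max_step_uv`, (b) the peak-to-peak range over the whole segment
#' exceeds `max_range_uv`, or (c) the peak-to-peak amplitude within any
#' sliding 100-ms interval falls below `min_activity_uv` (flat signal).
#'
#' @param e an [epochs()] object (epoch length must be at least the activity
#'   window).
#' @param rules a [rejection_rules()].
#' @return list with `epochs` (retained trials only, history appended) and
#'   `report`: data.frame subject/trial/condition/kept/rule_violated (first
#'   rule in a-b-c order when several fire).
#' @export
reject_artefacts <- function(e, rules = rejection_rules()) {
  d <- dim(e$data)
  win <- as.integer(round(rules$activity_window_ms / 1000 * e$fs)) + 1L
  if (win > d[3]) stop("epoch shorter than the activity window")
  viol <- scan_artefacts_cpp(e$data, d, rules$max_step_uv, rules$max_range_uv,
                             rules$min_activity_uv, win)
  rule <- apply(viol, 1, function(v)
    if (!any(v == 1)) NA_character_ else c("step", "range", "activity")[which(v == 1)[1]])
  kept <- is.na(rule)
  report <- data.frame(subject = e$subject_id, trial = seq_len(d[1]),
                       condition = e$conditions, kept = kept,
                       rule_violated = rule)
  e$data <- e$data[kept, , , drop = FALSE]
  e$conditions <- e$conditions[kept]
  e <- .append_history(e, "reject_artefacts",
                       list(rules = unclass(rules), n_rejected = sum(!kept)))
  list(epochs = e, report = report)
}

#' Segment a continuous recording into epochs
#'
#' Cuts fixed-length windows around event onsets. Endpoints are inclusive:
#' an epoch spans `round((t1 - t0)/1000 * fs) + 1` samples; the sample-time
#' mapping rounds half away from zero.
#'
#' @param continuous channels x samples matrix.
#' @param events integer vector of onset sample indices (1-based).
#' @param window ms pair relative to onset.
#' @param fs sampling rate, Hz.
#' @param channels channel labels (defaults to rownames or Ch1..ChN).
#' @param conditions per-event condition labels.
#' @return an [epochs()] object.
#' @export
segment_epochs <- function(continuous, events, window, fs,
                           channels = NULL, conditions = NULL) {
  stopifnot(is.matrix(continuous))
  if (is.null(channels))
    channels <- rownames(continuous) %||% paste0("Ch", seq_len(nrow(continuous)))
  if (is.null(conditions)) conditions <- rep("event", length(events))
  ns <- epoch_sample_count(window, fs)
  off0 <- .round_half_away(window[1] / 1000 * fs)
  for (i in seq_along(events)) {
    a <- events[i] + off0
    if (a < 1 || a + ns - 1 > ncol(continuous))
      stop("event ", i, " at sample ", events[i],
           " has an epoch window outside the recording")
  }
  data <- array(0, c(length(events), nrow(continuous), ns))
  for (i in seq_along(events)) {
    a <- events[i] + off0
    data[i, , ] <- continuous[, a:(a + ns - 1)]
  }
  epochs(data, fs = fs, t0 = off0 * 1000 / fs, conditions = conditions,
         channels = channels,
         history = list(list(op = "segment", params = list(window = window))))
}

.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Record that ocular ICA correction was not applied
#'
#' Ocular artefact correction by independent component analysis is a manual,
#' visually guided step and is outside the scope of this package; this no-op
#' documents its absence in the processing history so provenance logs are
#' explicit about it.
#'
#' @param e an [epochs()] object.
#' @return `e` with a history entry appended.
#' @export
skip_ica <- function(e) {
  .append_history(e, "ica_ocular_correction",
                  list(applied = FALSE, reason = "manual step; not implemented"))
}
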