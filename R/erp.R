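#' Grand-average evoked responses across subjects
#'
#' Unweighted mean across subjects within each condition, plus the
#' condition-collapsed grand average (unweighted mean of the four condition
#' grand averages) used for orthogonal electrode selection.
#'
#' @param evokeds list of per-subject `evoked` objects (possibly several
#'   conditions per subject).
#' @return list with `by_condition` (named list of `evoked`) and `collapsed`
#'   (single `evoked`).
#' @export
grand_average <- function(evokeds) {
  stopifnot(length(evokeds) >= 1)
  ref <- evokeds[[1]]
  for (ev in evokeds) {
    if (!identical(ev$channels, ref$channels))
      stop("evokeds have mismatched channels")
    if (ev$fs != ref$fs || ev$t0 != ref$t0)
      stop("evokeds have mismatched time axes")
  }
  conds <- unique(vapply(evokeds, `[[`, "", "condition"))
  by_condition <- list()
  for (cond in conds) {
    sel <- Filter(function(ev) ev$condition == cond, evokeds)
    m <- Reduce(`+`, lapply(sel, `[[`, "data")) / length(sel)
    by_condition[[cond]] <- structure(
      list(data = m, condition = cond, n_trials = length(sel), fs = ref$fs,
           t0 = ref$t0, channels = ref$channels, subject_id = "grand"),
      class = "evoked")
  }
  collapsed_data <- Reduce(`+`, lapply(by_condition, `[[`, "data")) /
    length(by_condition)
  collapsed <- structure(
    list(data = collapsed_data, condition = "collapsed",
         n_trials = length(by_condition), fs = ref$fs, t0 = ref$t0,
         channels = ref$channels, subject_id = "grand"),
    class = "evoked")
  list(by_condition = by_condition, collapsed = collapsed)
}

#' Select an electrode pool from the condition-collapsed topography
#'
#' Returns the `k` channels with the largest window-mean amplitude in the
#' collapsed grand average. Selection is independent of condition
#' differences by construction (the collapsed map is invariant to permuting
#' condition labels). Ties break by channel-label order.
#'
#' @param collapsed a condition-collapsed `evoked`.
#' @param window ms pair.
#' @param k number of electrodes.
#' @param exclude channels never selected (e.g. earlobe references).
#' @return character vector of `k` channel labels, in decreasing amplitude.
#' @export
select_pool_from_topography <- function(collapsed, window, k,
                                        exclude = c("A1", "A2")) {
  idx <- .window_idx(collapsed, window)
  keep <- !(collapsed$channels %in% exclude)
  if (k > sum(keep)) stop("k exceeds the number of selectable channels")
  wm <- rowMeans(collapsed$data[keep, idx, drop = FALSE])
  labs <- collapsed$channels[keep]
  ord <- order(-wm, labs)   # deterministic lexicographic tie-break
  labs[ord][seq_len(k)]
}

#' Pooled window-mean amplitude
#'
#' Averages the listed channels, then the in-window samples (endpoints
#' inclusive). For an `epochs` object a value per trial is returned; for an
#' `evoked`, a scalar.
#'
#' @param x an [epochs()] or `evoked` object.
#' @param electrodes channel labels to pool.
#' @param window ms pair.
#' @return numeric vector (per trial) or scalar, microvolts.
#' @export
pool_mean_amplitude <- function(x, electrodes, window) {
  for (el in electrodes)
    if (!el %in% x$channels) stop("unknown electrode: ", el)
  ic <- match(electrodes, x$channels)
  idx <- .window_idx(x, window)
  if (inherits(x, "evoked"))
    return(mean(x$data[ic, idx, drop = FALSE]))
  rowMeans(x$data[, ic, idx, drop = FALSE], dims = 1)
}

#' Component definitions for the amplitude table
#'
#' @param p3_window,lpp_early_window,lpp_late_window analysis windows (ms).
#' @param p3_pool,lpp_pool electrode pools.
#' @return named list of component definitions (window + pool).
#' @export
component_windows <- function(p3_window = c(250, 500),
                              lpp_early_window = c(650, 900),
                              lpp_late_window = c(900, 1150),
                              p3_pool = c("PZ", "CPZ", "CP2", "P2"),
                              lpp_pool = c("FCZ", "FC2", "C2")) {
  list(P3 = list(window = p3_window, pool = p3_pool),
       LPP_early = list(window = lpp_early_window, pool = lpp_pool),
       LPP_late = list(window = lpp_late_window, pool = lpp_pool))
}

#' Build the subject x condition x component amplitude table
#'
#' For each subject and condition, averages the retained trials into a
#' subject evoked response and extracts pooled window-mean amplitudes for
#' each component definition.
#'
#' @param evokeds_by_subject list (one element per subject) of named lists
#'   of `evoked` objects, one per condition.
#' @param components a [component_windows()] list.
#' @return data.frame with subject, condition, component, window, electrodes
#'   and `amplitude_uv`; one row per subject x condition x component.
#' @export
build_amplitude_table <- function(evokeds_by_subject,
                                  components = component_windows()) {
  rows <- list()
  for (s in seq_along(evokeds_by_subject)) {
    evs <- evokeds_by_subject[[s]]
    for (cond in names(evs)) {
      ev <- evs[[cond]]
      if (is.null(ev)) next
      for (comp in names(components)) {
        def <- components[[comp]]
        rows[[length(rows) + 1]] <- data.frame(
          subject = ev$subject_id, condition = cond, component = comp,
          window_start_ms = def$window[1], window_end_ms = def$window[2],
          electrodes = paste(def$pool, collapse = "/"),
          amplitude_uv = pool_mean_amplitude(ev, def$pool, def$window))
      }
    }
  }
  do.call(rbind, rows)
}

#' Subject-level evoked responses per condition from preprocessed epochs
#'
#' @param e an [epochs()] object after preprocessing/rejection.
#' @param warn_empty warn (and drop) conditions with no retained trials.
#' @return named list of `evoked`, one per condition present.
#' @export
evokeds_by_condition <- function(e, warn_empty = TRUE) {
  out <- list()
  for (cond in CONDITIONS) {
    n <- sum(e$conditions == cond)
    if (n == 0) {
      if (warn_empty)
        warning("subject ", e$subject_id, ": no retained trials in condition '",
                cond, "'; excluded")
      next
    }
    out[[cond]] <- compute_evoked(e, cond)
  }
  out
}

#' Amplitude table for a whole (in-memory or on-disk) study
#'
#' Convenience wrapper: preprocesses every subject (re-reference, filter,
#' baseline, artefact rejection), averages per condition and extracts the
#' component amplitude table.
#'
#' @param study result of [simulate_study()] (in-memory or with file stems).
#' @param components a [component_windows()] list.
#' @param rules a [rejection_rules()].
#' @param filter apply the band-pass/notch stage (slowest step; can be
#'   disabled for quick checks).
#' @return list with `table` (amplitude data.frame), `evokeds` (per-subject
#'   condition evokeds), `rejections` (pooled rejection report).
#' @export
study_amplitudes <- function(study, components = component_windows(),
                             rules = rejection_rules(), filter = TRUE) {
  evs <- list()
  reports <- list()
  for (s in seq_along(study$subjects)) {
    sub <- study$subjects[[s]]
    e <- if (is.character(sub)) read_epochs(sub) else sub$epochs
    e <- preprocess_epochs(e, rules = rules, filter = filter)
    reports[[s]] <- attr(e, "rejection_report")
    evs[[s]] <- evokeds_by_condition(e)
  }
  list(table = build_amplitude_table(evs, components), evokeds = evs,
       rejections = do.call(rbind, reports))
}

#' Standard preprocessing chain for one subject
#'
#' Re-reference to linked earlobes, notch + band-pass filter, segment-level
#' baseline correction, then threshold-based artefact rejection; earlobe
#' channels are dropped after re-referencing.
#'
#' @param e raw [epochs()] including earlobe channels.
#' @param rules a [rejection_rules()].
#' @param band,notch filter settings (see [filter_epochs()]).
#' @param baseline_window ms pair for [baseline_correct()].
#' @param filter apply the filtering stage.
#' @return preprocessed `epochs` (scalp channels only); the rejection report
#'   is attached as attribute `rejection_report`.
#' @export
preprocess_epochs <- function(e, rules = rejection_rules(),
                              band = c(0.01, 30), notch = 50,
                              baseline_window = NULL, filter = TRUE) {
  if (all(c("A1", "A2") %in% e$channels)) {
    e <- rereference_earlobes(e)
    keep <- !(e$channels %in% c("A1", "A2"))
    e$data <- e$data[, keep, , drop = FALSE]
    e$channels <- e$channels[keep]
  }
  if (filter) e <- filter_epochs(e, band = band, notch = notch)
  e <- skip_ica(e)
  if (is.null(baseline_window)) baseline_window <- c(e$t0, 0)
  e <- baseline_correct(e, baseline_window)
  rej <- reject_artefacts(e, rules)
  out <- rej$epochs
  attr(out, "rejection_report") <- rej$report
  out
}
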