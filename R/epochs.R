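#' Construct an epoch set
#'
#' The central container for segmented EEG: a `trials x channels x samples`
#' array of voltages in microvolts together with its sampling and labelling
#' metadata. All preprocessing and analysis functions consume and return
#' this class, appending a record of what they did to `history`.
#'
#' @param data numeric array, trials x channels x samples (microvolts).
#' @param fs sampling rate in Hz.
#' @param t0 epoch start in ms relative to stimulus onset (e.g. -200).
#' @param conditions character vector, one label per trial.
#' @param channels character vector of channel labels, one per channel.
#' @param subject_id subject identifier.
#' @param history list of previously applied operations.
#' @return an object of class `epochs`.
#' @export
epochs <- function(data, fs, t0, conditions, channels, subject_id = NA,
                   history = list()) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  stopifnot(all(is.finite(data)))
  stopifnot(dim(data)[1] == length(conditions),
            dim(data)[2] == length(channels))
  stopifnot(fs > 0)
  structure(list(data = data, fs = fs, t0 = t0,
                 conditions = as.character(conditions),
                 channels = as.character(channels),
                 subject_id = subject_id, history = history),
            class = "epochs")
}

#' @export
print.epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("epochs: %d trials x %d channels x %d samples @ %g Hz, t0 = %g ms\n",
              d[1], d[2], d[3], x$fs, x$t0))
  cat("conditions:", paste(sprintf("%s(%d)", names(table(x$conditions)),
                                   table(x$conditions)), collapse = " "), "\n")
  if (length(x$history))
    cat("history:", paste(vapply(x$history, `[[`, "", "op"), collapse = " -> "), "\n")
  invisible(x)
}

#' Time axis of an epoch set
#'
#' @param e an `epochs` object (or any list with `fs`, `t0` and a data array).
#' @return numeric vector of sample times in ms.
#' @export
epoch_times <- function(e) {
  n <- if (is.matrix(e$data)) ncol(e$data) else dim(e$data)[3]
  e$t0 + (seq_len(n) - 1) * 1000 / e$fs
}

# indices of samples with t_start <= t <= t_end (inclusive endpoints)
.window_idx <- function(e, window) {
  stopifnot(length(window) == 2, window[1] <= window[2])
  tt <- epoch_times(e)
  idx <- which(tt >= window[1] - 1e-9 & tt <= window[2] + 1e-9)
  if (!length(idx)) stop("window [", window[1], ", ", window[2],
                         "] ms contains no samples")
  idx
}

.append_history <- function(e, op, params = list()) {
  e$history <- c(e$history, list(list(op = op, params = params)))
  e
}

#' Write an epoch set to disk
#'
#' Stable on-disk container: a flat little-endian float64 binary holding the
#' data array in R's column-major order (`<stem>.bin`) and a JSON sidecar
#' (`<stem>.json`) with dimensions, sampling metadata, per-trial condition
#' labels, channel names, subject id and any seed recorded in the history.
#'
#' @param e an `epochs` object.
#' @param stem file path without extension.
#' @return `stem`, invisibly.
#' @export
write_epochs <- function(e, stem) {
  dir.create(dirname(stem), recursive = TRUE, showWarnings = FALSE)
  bin <- paste0(stem, ".bin")
  con <- file(bin, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.vector(e$data), con, size = 8, endian = "little")
  meta <- list(format = "erppipe-epochs-v1",
               dim = dim(e$data), fs = e$fs, t0 = e$t0,
               conditions = e$conditions, channels = e$channels,
               subject_id = e$subject_id, history = e$history)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(stem)
}

#' Read an epoch set written by [write_epochs()]
#'
#' @param stem file path without extension.
#' @return an `epochs` object.
#' @export
read_epochs <- function(stem) {
  jso <- paste0(stem, ".json")
  bin <- paste0(stem, ".bin")
  if (!file.exists(jso) || !file.exists(bin))
    stop("epoch container not found at stem: ", stem)
  meta <- jsonlite::read_json(jso, simplifyVector = TRUE)
  d <- as.integer(meta$dim)
  con <- file(bin, "rb")
  on.exit(close(con), add = TRUE)
  x <- readBin(con, "double", n = prod(d), size = 8, endian = "little")
  if (length(x) != prod(d)) stop("truncated epoch binary: ", bin)
  hist <- meta$history
  if (is.null(hist)) hist <- list()
  if (is.data.frame(hist)) hist <- lapply(seq_len(nrow(hist)), function(i) as.list(hist[i, ]))
  epochs(array(x, d), fs = meta$fs, t0 = meta$t0,
         conditions = meta$conditions, channels = meta$channels,
         subject_id = meta$subject_id, history = hist)
}

#' Average epochs into an evoked response
#'
#' @param e an `epochs` object.
#' @param condition optional condition label; if given only those trials are
#'   averaged.
#' @return an object of class `evoked`: list with `data`
#'   (channels x samples), `condition`, `n_trials`, `fs`, `t0`, `channels`.
#' @export
compute_evoked <- function(e, condition = NULL) {
  keep <- if (is.null(condition)) seq_along(e$conditions) else
    which(e$conditions == condition)
  if (!length(keep)) stop("no trials for condition: ", condition)
  m <- colMeans(e$data[keep, , , drop = FALSE], dims = 1)
  structure(list(data = m, condition = if (is.null(condition)) "all" else condition,
                 n_trials = length(keep), fs = e$fs, t0 = e$t0,
                 channels = e$channels, subject_id = e$subject_id),
            class = "evoked")
}

#' @export
print.evoked <- function(x, ...) {
  cat(sprintf("evoked '%s': %d channels x %d samples (%d trials) @ %g Hz\n",
              x$condition, nrow(x$data), ncol(x$data), x$n_trials, x$fs))
  invisible(x)
}
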