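#' Trial-epoched multichannel data
#'
#' Container for trials x channels x time data with sampling rate, epoch
#' time base (seconds relative to the event at t = 0), channel/ROI labels
#' and per-trial annotations (trial roster columns). Sample windows use the
#' half-open convention `[start, stop)` with 0-based sample indexing; all
#' operations that transform epochs append a step description to the
#' `log` attribute so a preprocessing chain is self-documenting.
#'
#' @param data numeric array, trials x channels x time.
#' @param fs sampling rate in Hz.
#' @param t_start time of the first sample in seconds relative to the event.
#' @param labels channel labels (length = dim 2).
#' @param annotations optional data frame with one row per trial.
#' @param baseline optional `c(start, stop)` baseline window in seconds.
#' @param log character vector of applied processing steps.
#' @return An object of class `epochs`.
#' @export
epochs <- function(data, fs, t_start = 0, labels = NULL, annotations = NULL,
                   baseline = NULL, log = character()) {
  if (length(dim(data)) != 3L) stopf("data must be trials x channels x time")
  if (!is.numeric(fs) || fs <= 0) stopf("fs must be positive")
  nt <- dim(data)[1]; cc <- dim(data)[2]
  labels <- labels %||% paste0("ch", seq_len(cc))
  if (length(labels) != cc) stopf("labels must have length %d", cc)
  if (anyDuplicated(labels)) stopf("labels must be unique")
  if (!is.null(annotations)) {
    annotations <- as.data.frame(annotations)
    if (nrow(annotations) != nt) {
      stopf("annotations must have %d rows (one per trial)", nt)
    }
  }
  structure(list(data = data, fs = fs, t_start = t_start, labels = labels,
                 annotations = annotations, baseline = baseline, log = log),
            class = "epochs")
}

#' @export
print.epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Epochs: %d trials x %d channels x %d samples @ %g Hz, t = [%g, %g) s\n",
              d[1], d[2], d[3], x$fs, x$t_start, x$t_start + d[3] / x$fs))
  if (!is.null(x$annotations)) {
    cat("  annotations:", paste(names(x$annotations), collapse = ", "), "\n")
  }
  if (length(x$log)) cat("  log:", paste(x$log, collapse = " | "), "\n")
  invisible(x)
}

#' @rdname epochs
#' @param x an `epochs` object.
#' @export
n_trials <- function(x) dim(x$data)[1]

#' @rdname epochs
#' @export
epoch_times <- function(x) x$t_start + (seq_len(dim(x$data)[3]) - 1L) / x$fs

## half-open sample window [start, stop) for a time interval in seconds
time_to_samples <- function(x, window) {
  tt <- epoch_times(x)
  which(tt >= window[1] - 1e-9 & tt < window[2] - 1e-9)
}

## subset trials, keeping annotations aligned
subset_trials <- function(x, idx) {
  epochs(x$data[idx, , , drop = FALSE], fs = x$fs, t_start = x$t_start,
         labels = x$labels,
         annotations = if (!is.null(x$annotations))
           x$annotations[idx, , drop = FALSE],
         baseline = x$baseline,
         log = c(x$log, sprintf("subset %d trials", length(idx))))
}

## subset channels
subset_channels <- function(x, idx) {
  if (is.character(idx)) idx <- match(idx, x$labels)
  epochs(x$data[, idx, , drop = FALSE], fs = x$fs, t_start = x$t_start,
         labels = x$labels[idx], annotations = x$annotations,
         baseline = x$baseline,
         log = c(x$log, sprintf("subset %d channels", length(idx))))
}

append_log <- function(x, msg) {
  x$log <- c(x$log, msg)
  x
}
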