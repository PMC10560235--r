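#' Congruency mismatch difference wave
#'
#' Computes the congruent-minus-incongruent evoked-response difference wave.
#' Trial-averaged ERPs per condition are band-pass filtered (zero-phase
#' Kaiser FIR, 0.5-50 Hz by default) and the two conditions are matched by
#' VOT rank before subtraction: the incongruent trials with the shortest VOT
#' are paired with the congruent trials with the shortest VOT, and so on, so
#' that VOT-driven latency shifts cancel in the contrast. Condition counts
#' must balance after matching.
#'
#' @param ep an [epochs()] object whose annotations carry `congruency` and
#'   `vot_ms` (see [label_congruency()]).
#' @param filter list with `low`, `high`, `taps`, `kaiser_beta` for the ERP
#'   filter, or `NULL` to skip filtering.
#' @return Object of class `difference_wave`: `values` (channels x time,
#'   congruent minus incongruent), `times`, `labels`,
#'   `n_congruent`, `n_incongruent`.
#' @export
mismatch_difference <- function(ep, filter = list(low = 0.5, high = 50,
                                                  taps = 3624,
                                                  kaiser_beta = 5.65)) {
  stopifnot(inherits(ep, "epochs"))
  ann <- ep$annotations
  if (is.null(ann) || !all(c("congruency", "vot_ms") %in% names(ann))) {
    stopf("epochs must carry congruency and vot_ms annotations")
  }
  ic <- which(ann$congruency == "congruent")
  ii <- which(ann$congruency == "incongruent")
  if (length(ic) != length(ii)) {
    stopf("unbalanced conditions after matching: %d congruent vs %d incongruent",
          length(ic), length(ii))
  }
  if (!length(ic)) stopf("no labeled trials for the contrast")
  ## match by VOT rank (shortest with shortest)
  ic <- ic[order(ann$vot_ms[ic])]
  ii <- ii[order(ann$vot_ms[ii])]
  cc <- dim(ep$data)[2]
  erp_c <- matrix(apply(ep$data[ic, , , drop = FALSE], c(2, 3), mean),
                  nrow = cc)
  erp_i <- matrix(apply(ep$data[ii, , , drop = FALSE], c(2, 3), mean),
                  nrow = cc)
  if (!is.null(filter)) {
    erp_c <- fir_bandpass(erp_c, fs = ep$fs, low = filter$low,
                          high = filter$high, taps = filter$taps,
                          kaiser_beta = filter$kaiser_beta)
    erp_i <- fir_bandpass(erp_i, fs = ep$fs, low = filter$low,
                          high = filter$high, taps = filter$taps,
                          kaiser_beta = filter$kaiser_beta)
    erp_c <- matrix(erp_c, nrow = cc)
    erp_i <- matrix(erp_i, nrow = cc)
  }
  structure(list(values = erp_c - erp_i, times = epoch_times(ep),
                 labels = ep$labels, n_congruent = length(ic),
                 n_incongruent = length(ii),
                 contrast = "congruent - incongruent (VOT rank matched)"),
            class = "difference_wave")
}

#' @export
print.difference_wave <- function(x, ...) {
  cat(sprintf("Difference wave (%s): %d channels, %d/%d trials per condition\n",
              x$contrast, nrow(x$values), x$n_congruent, x$n_incongruent))
  invisible(x)
}

#' Evoked-response peak latencies and amplitudes per VOT step
#'
#' For each VOT continuum step, measures on the trial-averaged (and
#' channel-averaged) evoked response: peak 1, the negative deflection in
#' `peak1_window` (default 175-325 ms, i.e. around 250 ms), and peak 2, the
#' positive deflection in `peak2_window` (default 275-425 ms, around
#' 350 ms). Flat segments are resolved to the earliest extremum and flagged.
#'
#' @param ep an [epochs()] with `vot_step` annotations.
#' @param peak1_window,peak2_window search windows in seconds.
#' @param channels channels to average over (labels or indices); default all.
#' @return Object of class `peak_measures`: data frame with one row per VOT
#'   step (`vot_step`, `n_trials`, `lat1_s`, `amp1`, `lat2_s`, `amp2`,
#'   `flat1`, `flat2`).
#' @export
vot_peak_measures <- function(ep, peak1_window = c(0.175, 0.325),
                              peak2_window = c(0.275, 0.425),
                              channels = NULL) {
  stopifnot(inherits(ep, "epochs"))
  ann <- ep$annotations
  if (is.null(ann) || !"vot_step" %in% names(ann)) {
    stopf("epochs must carry vot_step annotations")
  }
  if (!is.null(channels)) ep <- subset_channels(ep, channels)
  tt <- epoch_times(ep)
  i1 <- time_to_samples(ep, peak1_window)
  i2 <- time_to_samples(ep, peak2_window)
  if (!length(i1) || !length(i2)) stopf("empty peak search window")
  steps <- sort(unique(ann$vot_step[!is.na(ann$vot_step)]))
  res <- lapply(steps, function(s) {
    idx <- which(ann$vot_step == s)
    erp <- colMeans(matrix(apply(ep$data[idx, , , drop = FALSE],
                                 c(2, 3), mean), nrow = dim(ep$data)[2]))
    seg1 <- erp[i1]; seg2 <- erp[i2]
    flat1 <- diff(range(seg1)) < .Machine$double.eps^0.5
    flat2 <- diff(range(seg2)) < .Machine$double.eps^0.5
    k1 <- which.min(seg1)  # earliest minimum on ties
    k2 <- which.max(seg2)
    data.frame(vot_step = s, n_trials = length(idx),
               lat1_s = tt[i1[k1]], amp1 = seg1[k1],
               lat2_s = tt[i2[k2]], amp2 = seg2[k2],
               flat1 = flat1, flat2 = flat2)
  })
  out <- do.call(rbind, res)
  if (any(out$flat1 | out$flat2)) {
    warnf("flat signal in a peak window; earliest extremum used")
  }
  class(out) <- c("peak_measures", "data.frame")
  out
}
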