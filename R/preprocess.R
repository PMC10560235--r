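## Signal conditioning chain: resampling, common-mode (first-PC) removal,
## zero-phase FIR filtering, epoching, ensemble normalization, channel
## selection and ROI averaging.

## Zero-phase application of a linear-phase FIR by multiplying the padded
## FFT with the filter's magnitude response (exact group-delay
## compensation). `x` is a vector or channels x time matrix.
fir_apply_zerophase <- function(x, h) {
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, 1) else x
  n <- ncol(X)
  pad <- length(h)
  nfft <- stats::nextn(n + 2L * pad, 2)
  Hmag <- Mod(stats::fft(c(h, rep(0, nfft - length(h)))))
  Xp <- cbind(matrix(0, nrow(X), pad), X, matrix(0, nrow(X), nfft - n - pad))
  ## FFT along time for all channels at once
  F <- stats::mvfft(t(Xp))
  Y <- Re(stats::mvfft(F * Hmag, inverse = TRUE)) / nfft
  out <- t(Y)[, pad + seq_len(n), drop = FALSE]
  if (vec) drop(out) else out
}

#' Zero-phase Kaiser-windowed FIR band-pass filter
#'
#' Designs a linear-phase FIR band-pass with a Kaiser window and applies it
#' with exact group-delay compensation (the signal is convolved with the
#' filter's zero-phase magnitude response, equivalent to shifting the
#' linear-phase output back by its delay). The defaults reproduce the ERP
#' filter used throughout the package: 0.5-50 Hz, 3624 taps, Kaiser
#' beta = 5.65.
#'
#' @param x numeric vector or channels x time matrix.
#' @param fs sampling rate in Hz.
#' @param low,high band edges in Hz (`0 <= low < high < fs/2`).
#' @param taps filter length in samples (>= 3).
#' @param kaiser_beta Kaiser window shape parameter.
#' @return Filtered data, same shape as `x`.
#' @export
fir_bandpass <- function(x, fs, low = 0.5, high = 50, taps = 3624,
                         kaiser_beta = 5.65) {
  if (!(low >= 0 && low < high && high < fs / 2)) {
    stopf("band [%g, %g] Hz must satisfy 0 <= low < high < fs/2 = %g",
          low, high, fs / 2)
  }
  if (taps < 3) stopf("taps must be >= 3")
  w <- signal::kaiser(taps, kaiser_beta)
  h <- if (low > 0) {
    signal::fir1(taps - 1, c(low, high) / (fs / 2), type = "pass",
                 window = w)
  } else {
    signal::fir1(taps - 1, high / (fs / 2), type = "low", window = w)
  }
  ## pin the DC gain to exactly zero for band-pass designs (the Kaiser
  ## transition band otherwise leaks a little of a constant offset through)
  if (low > 0) h <- h - sum(h) / length(h)
  fir_apply_zerophase(x, h)
}

#' Zero-phase FIR notch for line noise and harmonics
#'
#' Cascaded Kaiser-windowed band-stop filters at the line frequency and its
#' harmonics below Nyquist, applied with zero phase.
#'
#' @inheritParams fir_bandpass
#' @param line_freq line frequency in Hz (60 by default).
#' @param n_harmonics number of harmonics (including the fundamental).
#' @param bw half-bandwidth of each notch in Hz.
#' @export
notch_line <- function(x, fs, line_freq = 60, n_harmonics = 3, bw = 1,
                       taps = 1001, kaiser_beta = 5.65) {
  w <- signal::kaiser(taps, kaiser_beta)
  for (k in seq_len(n_harmonics)) {
    f <- line_freq * k
    if (f + bw >= fs / 2) break
    h <- signal::fir1(taps - 1, c(f - bw, f + bw) / (fs / 2), type = "stop",
                      window = w)
    x <- fir_apply_zerophase(x, h)
  }
  x
}

#' Downsample a recording with Kaiser anti-alias filtering
#'
#' Low-pass filters at 90% of the new Nyquist frequency (zero-phase Kaiser
#' FIR) and keeps every `fs/target_fs`-th sample. Only integer decimation
#' factors are supported (the pipeline uses 2000 -> 1000 -> 100 Hz).
#'
#' @param rec a [recording()].
#' @param target_fs target sampling rate in Hz (must divide `fs`).
#' @return The downsampled [recording()].
#' @export
resample_recording <- function(rec, target_fs) {
  stopifnot(inherits(rec, "recording"))
  if (target_fs > rec$fs) stopf("upsampling is not supported")
  if (isTRUE(all.equal(target_fs, rec$fs))) return(rec)
  q <- rec$fs / target_fs
  if (abs(q - round(q)) > 1e-9) {
    stopf("fs/target_fs = %g must be an integer decimation factor", q)
  }
  q <- as.integer(round(q))
  taps <- 20L * q + 1L
  w <- signal::kaiser(taps, 7.85)
  h <- signal::fir1(taps - 1, 0.9 / q, type = "low", window = w)
  filt <- fir_apply_zerophase(rec$samples, h)
  keep <- seq(1L, ncol(filt), by = q)
  recording(filt[, keep, drop = FALSE], fs = target_fs, labels = rec$labels,
            roi_map = rec$roi_map, units = rec$units)
}

#' Remove the dominant high-frequency common-mode component
#'
#' Computes the first principal direction of the channel covariance of the
#' high-pass filtered (> `hp_cutoff`) recording and projects it out of the
#' broadband signal, removing broadband artifacts that are rank-1 across
#' channels (shared line/amplifier noise).
#'
#' @param rec a [recording()] with at least 2 channels.
#' @param hp_cutoff high-pass cutoff in Hz used to isolate the artifact band
#'   for the covariance estimate.
#' @return The cleaned [recording()].
#' @export
remove_first_pc <- function(rec, hp_cutoff = 300) {
  stopifnot(inherits(rec, "recording"))
  if (nrow(rec$samples) < 2L) stopf("need >= 2 channels")
  if (hp_cutoff >= rec$fs / 2) stopf("hp_cutoff must be below Nyquist")
  taps <- 501L
  w <- signal::kaiser(taps, 5.65)
  h <- signal::fir1(taps - 1, hp_cutoff / (rec$fs / 2), type = "high",
                    window = w)
  hp <- fir_apply_zerophase(rec$samples, h)
  cv <- tcrossprod(hp) / ncol(hp)
  v <- eigen(cv, symmetric = TRUE)$vectors[, 1, drop = FALSE]
  cleaned <- rec$samples - v %*% crossprod(v, rec$samples)
  recording(cleaned, fs = rec$fs, labels = rec$labels, roi_map = rec$roi_map,
            units = rec$units)
}

#' Epoch a recording around events and baseline-correct
#'
#' Cuts trials in the half-open window `[window[1], window[2])` seconds
#' around each event onset and subtracts the per-channel mean over the
#' baseline window. Events whose epoch would extend beyond the recording are
#' dropped with a warning reporting the count.
#'
#' @param rec a [recording()].
#' @param events data frame with `onset_s` and optional annotation columns.
#' @param window epoch window in seconds relative to onset, e.g.
#'   `c(-0.15, 0.8)`.
#' @param baseline baseline window in seconds, e.g. `c(-0.15, 0)`; `NULL`
#'   skips baseline correction.
#' @return An [epochs()] object carrying the event annotation columns.
#' @export
epoch_and_baseline <- function(rec, events, window = c(-0.15, 0.8),
                               baseline = c(-0.15, 0)) {
  stopifnot(inherits(rec, "recording"))
  if (!"onset_s" %in% names(events)) stopf("events must have onset_s")
  n <- ncol(rec$samples)
  nsamp <- round((window[2] - window[1]) * rec$fs)
  start <- round(events$onset_s * rec$fs) + round(window[1] * rec$fs) + 1L
  ok <- start >= 1L & (start + nsamp - 1L) <= n
  if (any(!ok)) {
    warnf("dropped %d of %d events too close to the recording edge",
          sum(!ok), length(ok))
  }
  start <- start[ok]
  if (!length(start)) stopf("no events left after edge dropping")
  cc <- nrow(rec$samples)
  dat <- array(0, dim = c(length(start), cc, nsamp))
  for (i in seq_along(start)) {
    dat[i, , ] <- rec$samples[, start[i] + seq_len(nsamp) - 1L, drop = FALSE]
  }
  ep <- epochs(dat, fs = rec$fs, t_start = window[1], labels = rec$labels,
               annotations = events[ok, setdiff(names(events), "onset_s"),
                                    drop = FALSE],
               baseline = baseline,
               log = sprintf("epoched %d/%d events, window [%g, %g) s",
                             length(start), length(ok), window[1], window[2]))
  if (!is.null(baseline)) {
    bidx <- time_to_samples(ep, baseline)
    if (!length(bidx)) stopf("baseline window contains no samples")
    bmean <- apply(ep$data[, , bidx, drop = FALSE], c(1, 2), mean)
    ep$data <- ep$data - as.vector(bmean)  # recycles over time (dim 3)
    ep <- append_log(ep, sprintf("baseline [%g, %g) s subtracted",
                                 baseline[1], baseline[2]))
  }
  ep
}

#' Ensemble-normalize epochs for Granger causality analysis
#'
#' At every (channel, time point), subtracts the mean across trials and
#' divides by the standard deviation across trials, removing the
#' trial-locked evoked component so that the state-space model is fitted to
#' the induced (stochastic) dynamics.
#'
#' @param ep an [epochs()] object with >= 2 trials.
#' @return Normalized [epochs()]: ensemble mean 0, ensemble SD 1 everywhere.
#' @export
normalize_trials_for_cgc <- function(ep) {
  stopifnot(inherits(ep, "epochs"))
  nt <- n_trials(ep)
  if (nt < 2L) stopf("need >= 2 trials")
  mu <- apply(ep$data, c(2, 3), mean)
  sd_ <- apply(ep$data, c(2, 3), stats::sd)
  if (any(sd_ <= 0)) {
    bad <- which(sd_ <= 0, arr.ind = TRUE)[1, ]
    stopf("zero ensemble SD at channel %s, sample %d",
          ep$labels[bad[1]], bad[2])
  }
  dat <- ep$data
  for (i in seq_len(nt)) dat[i, , ] <- (dat[i, , ] - mu) / sd_
  ep$data <- dat
  append_log(ep, "ensemble normalized (mean 0, SD 1 across trials)")
}

#' Select speech-responsive channels
#'
#' A channel is selected when the magnitude of its trial-averaged response
#' deviates from the baseline mean by more than `k_sd` baseline standard
#' deviations for a cumulative duration of at least `min_duration` seconds
#' within the response window. The baseline SD is, by default, the SD across
#' time of the trial-averaged baseline segment.
#'
#' @param ep an [epochs()] object (baseline-corrected).
#' @param response_window window in seconds to search, default `c(0, 0.5)`
#'   (the target word).
#' @param min_duration minimum cumulative supra-threshold duration in
#'   seconds (default 0.125).
#' @param k_sd threshold in baseline SDs (default 2).
#' @param baseline baseline window; defaults to the epochs' stored baseline.
#' @return list with `selected` (labels), `report` (per-channel data frame
#'   with the supra-threshold duration).
#' @export
select_speech_responsive <- function(ep, response_window = c(0, 0.5),
                                     min_duration = 0.125, k_sd = 2,
                                     baseline = NULL) {
  stopifnot(inherits(ep, "epochs"))
  if (min_duration > diff(response_window)) {
    stopf("min_duration exceeds the response window")
  }
  baseline <- baseline %||% ep$baseline %||% c(ep$t_start, 0)
  erp <- apply(ep$data, c(2, 3), mean)   # channels x time
  bidx <- time_to_samples(ep, baseline)
  ridx <- time_to_samples(ep, response_window)
  if (!length(bidx) || !length(ridx)) stopf("empty baseline or response window")
  bmean <- rowMeans(erp[, bidx, drop = FALSE])
  bsd <- apply(erp[, bidx, drop = FALSE], 1, stats::sd)
  above <- abs(erp[, ridx, drop = FALSE] - bmean) > k_sd * bsd
  dur <- rowSums(above) / ep$fs
  sel <- dur >= min_duration
  list(selected = ep$labels[sel],
       report = data.frame(channel = ep$labels, supra_sd_duration_s = dur,
                           selected = sel))
}

#' Average channels into regions of interest
#'
#' Replaces channels by the per-trial mean over the member channels of each
#' ROI in the map; ROI labels replace channel labels.
#'
#' @param ep an [epochs()] object.
#' @param roi_map named character vector `channel -> ROI`; channels absent
#'   from the map are dropped.
#' @return ROI-level [epochs()].
#' @export
average_roi <- function(ep, roi_map) {
  stopifnot(inherits(ep, "epochs"))
  roi_map <- unlist(roi_map)
  rois <- unique(unname(roi_map))
  members <- lapply(rois, function(r) {
    intersect(ep$labels, names(roi_map)[roi_map == r])
  })
  empty <- lengths(members) == 0L
  if (any(empty)) {
    stopf("ROI(s) with no member channels: %s",
          paste(rois[empty], collapse = ", "))
  }
  d <- dim(ep$data)
  out <- array(0, dim = c(d[1], length(rois), d[3]))
  for (k in seq_along(rois)) {
    idx <- match(members[[k]], ep$labels)
    out[, k, ] <- if (length(idx) == 1L) ep$data[, idx, ] else
      apply(ep$data[, idx, , drop = FALSE], c(1, 3), mean)
  }
  epochs(out, fs = ep$fs, t_start = ep$t_start, labels = rois,
         annotations = ep$annotations, baseline = ep$baseline,
         log = c(ep$log, sprintf("averaged into %d ROIs", length(rois))))
}
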