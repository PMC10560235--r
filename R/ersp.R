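#' Event-related spectral perturbation (ERSP)
#'
#' Time-frequency power via Morlet wavelets (analytic, frequency-domain
#' implementation), averaged across trials and expressed in decibels
#' relative to the mean baseline power at each frequency:
#' `10 * log10(P(t, f) / mean_baseline P(f))`. By default the dB conversion
#' is applied to the trial-averaged power.
#'
#' @param ep an [epochs()] object.
#' @param freqs frequency grid in Hz; default 30 log-spaced points from 4 to
#'   `min(150, 0.9 * fs/2)`.
#' @param n_cycles Morlet cycles (wavelet sd in time is
#'   `n_cycles / (2 pi f)`).
#' @param baseline baseline window in seconds; defaults to the epochs'
#'   stored baseline window (`c(-0.15, 0)` for the standard epoching).
#' @param db_per_trial if `TRUE`, convert each trial's power to dB before
#'   averaging (alternative convention); default converts the trial-mean
#'   power.
#' @return Object of class `ersp`: list with `values` (channels x
#'   frequencies x time, dB), `freq`, `times`, `baseline`, `fs`, `labels`.
#' @export
compute_ersp <- function(ep, freqs = NULL, n_cycles = 7,
                         baseline = NULL, db_per_trial = FALSE) {
  stopifnot(inherits(ep, "epochs"))
  baseline <- baseline %||% ep$baseline %||% c(ep$t_start, 0)
  fmax <- min(150, 0.9 * ep$fs / 2)
  freqs <- freqs %||% exp(seq(log(4), log(fmax), length.out = 30))
  if (any(freqs <= 0 | freqs >= ep$fs / 2)) {
    stopf("freqs must lie strictly inside (0, fs/2)")
  }
  d <- dim(ep$data)
  nt <- d[1]; cc <- d[2]; n <- d[3]
  nfft <- stats::nextn(2L * n, 2)
  fgrid <- (seq_len(nfft) - 1L) / nfft * ep$fs
  ## analytic Morlet multipliers, one column per center frequency
  G <- matrix(0, nfft, length(freqs))
  pos <- fgrid <= ep$fs / 2
  for (k in seq_along(freqs)) {
    sig_t <- n_cycles / (2 * pi * freqs[k])
    G[pos, k] <- 2 * exp(-0.5 * ((fgrid[pos] - freqs[k]) * 2 * pi * sig_t)^2)
  }
  pw <- array(0, dim = c(cc, length(freqs), n))
  for (i in seq_len(nt)) {
    X0 <- matrix(ep$data[i, , ], nrow = cc)
    X <- stats::mvfft(t(cbind(X0, matrix(0, cc, nfft - n))))
    for (j in seq_len(cc)) {
      W <- stats::mvfft(G * X[, j], inverse = TRUE) / nfft
      Pj <- t(Mod(W[seq_len(n), , drop = FALSE])^2)  # freq x time -> t()
      pw[j, , ] <- pw[j, , ] + if (db_per_trial) log10(Pj) else Pj
    }
  }
  pw <- pw / nt
  bidx <- which(epoch_times(ep) >= baseline[1] - 1e-9 &
                epoch_times(ep) < baseline[2] - 1e-9)
  if (!length(bidx)) stopf("baseline window contains no samples")
  if (db_per_trial) {
    base <- apply(pw[, , bidx, drop = FALSE], c(1, 2), mean)
    vals <- 10 * (pw - as.vector(base))
  } else {
    base <- apply(pw[, , bidx, drop = FALSE], c(1, 2), mean)
    if (any(base <= 0)) stopf("zero baseline power at some frequency")
    vals <- 10 * (log10(pw) - as.vector(log10(base)))
  }
  structure(list(values = vals, freq = freqs, times = epoch_times(ep),
                 baseline = baseline, fs = ep$fs, labels = ep$labels),
            class = "ersp")
}

#' @export
print.ersp <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("ERSP: %d channels x %d frequencies (%.3g-%.3g Hz) x %d samples, dB re baseline [%g, %g) s\n",
              d[1], d[2], min(x$freq), max(x$freq), d[3],
              x$baseline[1], x$baseline[2]))
  invisible(x)
}

#' Average an ERSP over frequency bands
#'
#' Unweighted mean of the dB values over the frequency bins whose center
#' frequency lies inside each band (inclusive bounds).
#'
#' @param ersp an [compute_ersp()] result.
#' @param bands a [band_set()]; default [ersp_bands()].
#' @return Array channels x bands x time (dB) with band dimnames, plus
#'   `times` attribute.
#' @export
band_average <- function(ersp, bands = ersp_bands()) {
  stopifnot(inherits(ersp, "ersp"))
  d <- dim(ersp$values)
  out <- array(0, dim = c(d[1], length(bands), d[3]),
               dimnames = list(ersp$labels, names(bands), NULL))
  for (k in seq_along(bands)) {
    idx <- which(ersp$freq >= bands[[k]][1] - 1e-9 &
                 ersp$freq <= bands[[k]][2] + 1e-9)
    if (!length(idx)) {
      stopf("band '%s' (%g-%g Hz) contains no frequency bins",
            names(bands)[k], bands[[k]][1], bands[[k]][2])
    }
    out[, k, ] <- apply(ersp$values[, idx, , drop = FALSE], c(1, 3), mean)
  }
  attr(out, "times") <- ersp$times
  out
}
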