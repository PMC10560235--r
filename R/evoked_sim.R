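#' Specify synthetic evoked-response structure
#'
#' Parameters of the synthetic evoked responses generated by
#' [simulate_evoked_trials()]: two VOT-latency-shifted peaks (a negative
#' deflection around 250 ms and a positive one around 350 ms), a mismatch
#' component added to incongruent trials, optional band-limited power
#' effects per recording phase, and trial noise.
#'
#' @param peak1,peak2 lists with `latency` (s, for VOT step 1), `amplitude`
#'   (uV; negative for peak 1, positive for peak 2), `width` (Gaussian SD,
#'   s) and `vot_slope_ms` (latency shift per VOT step, ms).
#' @param mismatch list with `amplitude` (uV, added to incongruent trials)
#'   and `window` (`c(start, stop)` s; the component is a Gaussian centered
#'   in the window).
#' @param band_effects list of lists with `band` (`c(low, high)` Hz), `db`
#'   (power change in dB), `phase` (`"pre"`/`"post"`), `amplitude`
#'   (baseline uV RMS of the band-limited component).
#' @param noise_sd trial noise SD in uV (> 0).
#' @return Object of class `evoked_effect_spec`.
#' @export
evoked_effect_spec <- function(peak1 = list(latency = 0.25, amplitude = -8,
                                            width = 0.03, vot_slope_ms = 8),
                               peak2 = list(latency = 0.35, amplitude = 6,
                                            width = 0.04, vot_slope_ms = 8),
                               mismatch = list(amplitude = 4,
                                               window = c(0.27, 0.35)),
                               band_effects = list(),
                               noise_sd = 5) {
  if (noise_sd <= 0) stopf("noise_sd must be > 0")
  for (p in list(peak1, peak2)) {
    if (!all(c("latency", "amplitude", "width") %in% names(p))) {
      stopf("peaks need latency, amplitude, width")
    }
    if (p$width <= 0) stopf("peak width must be > 0")
  }
  if (!is.null(mismatch) && mismatch$window[1] >= mismatch$window[2]) {
    stopf("mismatch window must be increasing")
  }
  structure(list(peak1 = peak1, peak2 = peak2, mismatch = mismatch,
                 band_effects = band_effects, noise_sd = noise_sd),
            class = "evoked_effect_spec")
}

gauss_bump <- function(tt, center, width) exp(-0.5 * ((tt - center) / width)^2)

#' Simulate evoked-response trials from a roster
#'
#' Per trial: white noise (`noise_sd`) plus the two VOT-latency-shifted
#' peaks, plus the mismatch component on incongruent trials, plus any
#' band-limited components whose amplitude is scaled by the per-phase dB
#' effect. Non-experimental (filler/catch) trials receive noise only. The
#' ensemble average over trials of a cell therefore equals the deterministic
#' template within `noise_sd / sqrt(n)`.
#'
#' @param roster a (congruency-labeled) [make_task_roster()] roster.
#' @param spec an [evoked_effect_spec()].
#' @param fs sampling rate in Hz.
#' @param window epoch window in seconds, e.g. `c(-0.15, 0.8)`.
#' @param n_channels number of channels (independent noise, same template).
#' @param seed integer seed.
#' @return An [epochs()] object (trials x channels x time) carrying the
#'   roster as annotations, with baseline `c(window[1], 0)`.
#' @export
simulate_evoked_trials <- function(roster, spec, fs = 1000,
                                   window = c(-0.15, 0.8), n_channels = 1L,
                                   seed = 1) {
  stopifnot(inherits(roster, "trial_roster"),
            inherits(spec, "evoked_effect_spec"))
  n <- round((window[2] - window[1]) * fs)
  tt <- window[1] + (seq_len(n) - 1L) / fs
  if (!is.null(spec$mismatch)) {
    mw <- spec$mismatch$window
    if (mw[1] < window[1] || mw[2] > window[2]) {
      stopf("mismatch window [%g, %g] s lies outside the epoch [%g, %g] s",
            mw[1], mw[2], window[1], window[2])
    }
  }
  nt <- nrow(roster)
  template <- function(row) {
    y <- numeric(n)
    if (row$trial_class != "experimental") return(y)
    shift <- 0
    if (!is.na(row$vot_step)) {
      shift <- (row$vot_step - 1) * (spec$peak1$vot_slope_ms %||% 0) / 1000
    }
    y <- y + spec$peak1$amplitude *
      gauss_bump(tt, spec$peak1$latency + shift, spec$peak1$width)
    shift2 <- if (!is.na(row$vot_step)) {
      (row$vot_step - 1) * (spec$peak2$vot_slope_ms %||% 0) / 1000
    } else 0
    y <- y + spec$peak2$amplitude *
      gauss_bump(tt, spec$peak2$latency + shift2, spec$peak2$width)
    if (!is.null(spec$mismatch) && !is.na(row$congruency) &&
        row$congruency == "incongruent" && spec$mismatch$amplitude != 0) {
      mw <- spec$mismatch$window
      y <- y + spec$mismatch$amplitude *
        gauss_bump(tt, mean(mw), diff(mw) / 4)
    }
    y
  }
  dat <- with_seed(seed, {
    out <- array(stats::rnorm(nt * n_channels * n, sd = spec$noise_sd),
                 dim = c(nt, n_channels, n))
    for (i in seq_len(nt)) {
      tpl <- template(roster[i, ])
      for (ch in seq_len(n_channels)) {
        out[i, ch, ] <- out[i, ch, ] + tpl
      }
      for (be in spec$band_effects) {
        amp <- be$amplitude
        if (identical(be$phase, roster$phase[i])) {
          amp <- amp * 10^(be$db / 20)
        }
        if (amp > 0) {
          for (ch in seq_len(n_channels)) {
            bn <- stats::rnorm(n)
            bn <- fir_bandpass(bn, fs = fs, low = be$band[1],
                               high = be$band[2], taps = 257,
                               kaiser_beta = 5.65)
            post <- tt >= 0
            out[i, ch, post] <- out[i, ch, post] +
              amp * bn[post] / stats::sd(bn)
          }
        }
      }
    }
    out
  })
  epochs(dat, fs = fs, t_start = window[1],
         labels = paste0("HGsim", seq_len(n_channels)),
         annotations = as.data.frame(roster), baseline = c(window[1], 0),
         log = sprintf("simulated evoked trials (seed %d)", seed))
}
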