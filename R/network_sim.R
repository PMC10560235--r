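#' Specify a coupled stochastic-oscillator network
#'
#' Defines a linear network of damped stochastic oscillators with directed,
#' band-limited couplings, used to synthesize multichannel trial data with
#' known ground-truth directed influence. Each node is an AR(2) resonator
#' with poles at radius `damping` and angle `2*pi*f0/fs` (so its spectrum
#' peaks near `f0`). A coupling from node j to node i adds a short causal
#' cosine-burst kernel (centered on the coupling band's center frequency,
#' L2-normalized to `gain`) starting at lag `lag` samples, so the directed
#' influence j -> i is concentrated in `band`. Per-condition overrides allow
#' edges to be removed, added or rescaled between e.g. a "pre" and a "post"
#' recording condition.
#'
#' @param n_nodes number of nodes (channels).
#' @param f0 per-node center frequencies in Hz (recycled to `n_nodes`).
#' @param damping per-node pole radii in (0, 1) (recycled).
#' @param couplings data frame (or list coercible to one) with columns
#'   `source`, `target`, `gain`, `lag` (samples, >= 1), `band_low`,
#'   `band_high` (Hz).
#' @param noise_sd per-node innovation standard deviations (recycled).
#' @param fs sampling rate in Hz.
#' @param condition_deltas named list, one entry per condition name, each a
#'   data frame with the same columns as `couplings`; for matching
#'   (source, target) pairs the delta row replaces the base coupling (a gain
#'   of 0 removes the edge), unmatched delta rows are added.
#' @param labels optional node labels.
#' @return An object of class `network_spec`.
#' @examples
#' spec <- example_network_spec()
#' spec
#' @export
network_spec <- function(n_nodes, f0 = 10, damping = 0.85, couplings = NULL,
                         noise_sd = 1, fs = 100, condition_deltas = list(),
                         labels = NULL) {
  stopifnot(is_count(n_nodes), n_nodes >= 1)
  f0 <- rep_len(f0, n_nodes)
  damping <- rep_len(damping, n_nodes)
  noise_sd <- rep_len(noise_sd, n_nodes)
  if (any(damping <= 0 | damping >= 1)) stopf("damping must be in (0, 1)")
  if (any(noise_sd <= 0)) stopf("noise_sd must be positive")
  if (any(f0 < 0 | f0 > fs / 2)) stopf("f0 must be within [0, fs/2]")
  couplings <- normalize_couplings(couplings, n_nodes)
  condition_deltas <- lapply(condition_deltas, normalize_couplings, n_nodes)
  labels <- labels %||% paste0("node", seq_len(n_nodes))
  spec <- structure(list(n_nodes = as.integer(n_nodes), f0 = f0,
                         damping = damping, couplings = couplings,
                         noise_sd = noise_sd, fs = fs,
                         condition_deltas = condition_deltas,
                         labels = labels),
                    class = "network_spec")
  ## fail fast on unstable generators, naming the offending root
  for (cond in c(NA_character_, names(condition_deltas))) {
    network_var(spec, condition = if (is.na(cond)) NULL else cond)
  }
  spec
}

normalize_couplings <- function(couplings, n_nodes) {
  if (is.null(couplings) || (is.data.frame(couplings) && !nrow(couplings))) {
    return(data.frame(source = integer(), target = integer(),
                      gain = numeric(), lag = integer(),
                      band_low = numeric(), band_high = numeric()))
  }
  cp <- as.data.frame(couplings)
  need <- c("source", "target", "gain", "lag", "band_low", "band_high")
  if (!all(need %in% names(cp))) {
    stopf("couplings must have columns %s", paste(need, collapse = ", "))
  }
  cp <- cp[need]
  if (any(cp$lag < 1)) stopf("coupling lags must be >= 1 sample")
  if (any(!is.finite(cp$gain))) stopf("coupling gains must be finite")
  if (any(cp$source < 1 | cp$source > n_nodes |
          cp$target < 1 | cp$target > n_nodes)) {
    stopf("coupling node indices out of range")
  }
  if (any(cp$source == cp$target)) stopf("self-couplings are not allowed")
  cp
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("Oscillator network: %d nodes, fs = %g Hz, %d base coupling(s)\n",
              x$n_nodes, x$fs, nrow(x$couplings)))
  if (nrow(x$couplings)) {
    for (i in seq_len(nrow(x$couplings))) {
      cp <- x$couplings[i, ]
      cat(sprintf("  %s -> %s  gain %.3g, lag %d, band %g-%g Hz\n",
                  x$labels[cp$source], x$labels[cp$target], cp$gain,
                  as.integer(cp$lag), cp$band_low, cp$band_high))
    }
  }
  if (length(x$condition_deltas)) {
    cat("  conditions with coupling overrides:",
        paste(names(x$condition_deltas), collapse = ", "), "\n")
  }
  invisible(x)
}

## Effective coupling table for a condition: delta rows replace matching
## (source, target) base rows, rows with gain 0 drop the edge, unmatched
## delta rows are added.
effective_couplings <- function(spec, condition = NULL) {
  cp <- spec$couplings
  if (!is.null(condition)) {
    if (!condition %in% c("pre", names(spec$condition_deltas))) {
      stopf("unknown condition '%s'", condition)
    }
    dl <- spec$condition_deltas[[condition]]
    if (!is.null(dl) && nrow(dl)) {
      key <- function(d) paste(d$source, d$target)
      drop <- key(cp) %in% key(dl)
      cp <- rbind(cp[!drop, , drop = FALSE], dl)
    }
  }
  cp[cp$gain != 0, , drop = FALSE]
}

## Short causal cosine-burst FIR kernel at the band center frequency,
## Hann-windowed, L2-normalized to `gain`. Length: one carrier cycle,
## at least 2 and at most 6 taps (longer kernels raise the generator
## order beyond what moderate state dimensions can represent).
coupling_kernel <- function(gain, f_center, fs) {
  L <- max(2L, min(6L, round(fs / max(f_center, fs / 12))))
  k <- seq_len(L) - 1L
  h <- cos(2 * pi * f_center * k / fs) * (0.5 - 0.5 * cos(2 * pi * (k + 1) / (L + 1)))
  gain * h / sqrt(sum(h^2))
}

#' Ground-truth VAR form of a network specification
#'
#' Assembles the VAR coefficient array and innovation covariance implied by
#' a [network_spec()] under a given condition, checking stability of the
#' companion form. This is the exact generator used by
#' [simulate_network_trials()], and feeding it to [var_to_ss()] +
#' [spectral_cgc()] yields the theoretical (noise-free) directed-influence
#' spectra against which estimates can be compared.
#'
#' @param spec a [network_spec()].
#' @param condition condition name in `names(spec$condition_deltas)`, or
#'   `NULL`/`"pre"` for the base network.
#' @return list with `Acoef` (c x c x p), `Sigma` (diagonal), `fs`, `labels`.
#' @export
network_var <- function(spec, condition = NULL) {
  stopifnot(inherits(spec, "network_spec"))
  cc <- spec$n_nodes
  cp <- effective_couplings(spec, condition)
  p <- 2L
  kernels <- vector("list", nrow(cp))
  if (nrow(cp)) {
    for (i in seq_len(nrow(cp))) {
      fc <- (cp$band_low[i] + cp$band_high[i]) / 2
      kernels[[i]] <- coupling_kernel(cp$gain[i], fc, spec$fs)
      p <- max(p, cp$lag[i] + length(kernels[[i]]) - 1L)
    }
  }
  Acoef <- array(0, dim = c(cc, cc, p))
  th <- 2 * pi * spec$f0 / spec$fs
  for (i in seq_len(cc)) {
    Acoef[i, i, 1] <- 2 * spec$damping[i] * cos(th[i])
    Acoef[i, i, 2] <- -spec$damping[i]^2
  }
  if (nrow(cp)) {
    for (i in seq_len(nrow(cp))) {
      h <- kernels[[i]]
      idx <- cp$lag[i] + seq_along(h) - 1L
      Acoef[cp$target[i], cp$source[i], idx] <-
        Acoef[cp$target[i], cp$source[i], idx] + h
    }
  }
  ## companion-form stability check
  comp <- rbind(matrix(Acoef, cc, cc * p),
                cbind(diag(1, cc * (p - 1)), matrix(0, cc * (p - 1), cc)))
  ev <- eigen(comp, only.values = TRUE)$values
  rho <- max(Mod(ev))
  if (rho >= 1) {
    bad <- ev[which.max(Mod(ev))]
    stopf("unstable network%s: companion root %.4f%+.4fi has modulus %.4f",
          if (is.null(condition)) "" else sprintf(" (condition '%s')", condition),
          Re(bad), Im(bad), rho)
  }
  list(Acoef = Acoef, Sigma = diag(spec$noise_sd^2, cc), fs = spec$fs,
       labels = spec$labels)
}

#' @rdname network_var
#' @export
network_ss <- function(spec, condition = NULL) {
  v <- network_var(spec, condition)
  var_to_ss(v$Acoef, v$Sigma, fs = v$fs, labels = v$labels)
}

#' Simulate independent multichannel trials from a network specification
#'
#' Draws `n_trials` independent realizations of the network under the given
#' condition. Each trial starts from an independent burn-in (400 samples) so
#' trials are draws from the stationary distribution; there is no carry-over
#' across trials.
#'
#' @inheritParams network_var
#' @param n_trials number of trials.
#' @param n_samples samples per trial.
#' @param fs sampling rate; must equal `spec$fs` (the spec fixes the
#'   generator's time base).
#' @param seed integer seed (reproducible; independent of caller RNG state).
#' @param annotations optional data frame of per-trial annotations.
#' @return An [epochs()] object, trials x channels x time.
#' @export
simulate_network_trials <- function(spec, condition = NULL, n_trials = 100,
                                    n_samples = 200, fs = spec$fs,
                                    seed = 1, annotations = NULL) {
  stopifnot(inherits(spec, "network_spec"))
  if (!isTRUE(all.equal(fs, spec$fs))) {
    stopf("fs (%g) must match spec$fs (%g)", fs, spec$fs)
  }
  v <- network_var(spec, condition)
  cc <- spec$n_nodes; p <- dim(v$Acoef)[3]
  burn <- 400L
  ntot <- n_samples + burn
  Amat <- matrix(v$Acoef, cc, cc * p)  # (A_1 ... A_p)
  sds <- spec$noise_sd
  dat <- with_seed(seed, {
    ## vectorized across trials: one time loop, all trials as columns
    Y <- array(0, dim = c(cc, n_trials, ntot))
    lagbuf <- matrix(0, cc * p, n_trials)  # (y_{t-1}; ...; y_{t-p})
    for (t in seq_len(ntot)) {
      eps <- matrix(stats::rnorm(cc * n_trials, sd = sds), cc, n_trials)
      yt <- Amat %*% lagbuf + eps
      Y[, , t] <- yt
      if (p > 1L) {
        lagbuf <- rbind(yt, lagbuf[seq_len(cc * (p - 1L)), , drop = FALSE])
      } else {
        lagbuf <- yt
      }
    }
    Y[, , burn + seq_len(n_samples), drop = FALSE]
  })
  dat <- aperm(dat, c(2, 1, 3))  # trials x channels x time
  epochs(dat, fs = spec$fs, t_start = 0, labels = spec$labels,
         annotations = annotations)
}

#' Five-node two-condition example network
#'
#' A ready-made [network_spec()] mirroring a pre/post disconnection design:
#' five nodes labeled after the recorded regions (IFGop, IFGtri, STG, HG,
#' TP-analog), with a beta-band edge IFGop -> IFGtri, a theta-band edge
#' IFGop -> STG, and a gamma-band edge HG -> TP-analog that is removed in
#' the `"post"` condition. The removed edge is incident only to nodes that
#' carry no other couplings, so the pre/post difference in ground-truth
#' directed influence is confined to that single edge.
#'
#' @param gamma_gain gain of the gamma edge present pre, absent post. The
#'   default is deliberately modest: the edge is still detected with
#'   essentially full power at the study's trial counts, while keeping the
#'   shared variance between its endpoints small enough that the remaining
#'   network's estimates are unaffected by the manipulation.
#' @param fs sampling rate in Hz.
#' @return A `network_spec` with conditions `"pre"` (base) and `"post"`.
#' @export
example_network_spec <- function(gamma_gain = 0.12, fs = 100) {
  couplings <- data.frame(
    source = c(1L, 1L, 4L),
    target = c(2L, 3L, 5L),
    gain = c(0.6, 0.6, gamma_gain),
    lag = c(2L, 2L, 1L),
    band_low = c(13, 4, 31),
    band_high = c(30, 8, 50))
  post <- data.frame(source = 4L, target = 5L, gain = 0,
                     lag = 1L, band_low = 31, band_high = 50)
  network_spec(
    n_nodes = 5L,
    f0 = c(20, 22, 6, 40, 38),
    damping = c(0.8, 0.75, 0.75, 0.8, 0.75),
    couplings = couplings,
    noise_sd = 1,
    fs = fs,
    condition_deltas = list(post = post),
    labels = c("IFGop", "IFGtri", "STG", "HG", "TPa"))
}
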