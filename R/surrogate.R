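#' Phase-randomization surrogate epochs
#'
#' Replaces the Fourier phases of every trial and channel independently by
#' i.i.d. uniform phases (conjugate-symmetric, DC and Nyquist bins kept
#' real), preserving each channel's amplitude spectrum to machine precision
#' while destroying cross-channel dependence in expectation. Used to build
#' empirical null distributions for connectivity measures.
#'
#' @param ep an [epochs()] object.
#' @param seed integer seed.
#' @return Surrogate [epochs()] of the same shape.
#' @export
phase_randomize <- function(ep, seed = 1) {
  stopifnot(inherits(ep, "epochs"))
  d <- dim(ep$data)
  nt <- d[1]; cc <- d[2]; n <- d[3]
  half <- (n - 1L) %/% 2L          # freely randomizable bins 2..half+1
  even <- n %% 2L == 0L
  out <- ep$data
  with_seed(seed, {
    for (i in seq_len(nt)) {
      X <- stats::mvfft(t(matrix(ep$data[i, , ], nrow = cc)))  # n x cc
      if (half > 0L) {
        ph <- matrix(stats::runif(half * cc, 0, 2 * pi), half, cc)
        rot <- exp(1i * ph)
        X[2:(half + 1L), ] <- Mod(X[2:(half + 1L), , drop = FALSE]) * rot
        hi <- n - (2:(half + 1L)) + 2L   # conjugate mirror indices
        X[hi, ] <- Conj(X[2:(half + 1L), , drop = FALSE])
      }
      if (even) {
        ny <- n %/% 2L + 1L
        X[ny, ] <- Mod(X[ny, , drop = FALSE]) *
          sign(Re(X[ny, , drop = FALSE]))
      }
      out[i, , ] <- t(Re(stats::mvfft(X, inverse = TRUE)) / n)
    }
  })
  ep$data <- out
  append_log(ep, sprintf("phase randomized (seed %d)", seed))
}

#' Surrogate significance threshold for GC spectra
#'
#' Builds an empirical null for each (source, target, frequency) cell by
#' re-running the full identification + spectral GC pipeline on `n_surr`
#' phase-randomized copies of the data (the same model order as the
#' observed fit is reused). The observed spectrum is thresholded at the
#' `1 - alpha` quantile of its cell-wise null: values below threshold are
#' set to zero, values above are reduced by the threshold.
#'
#' @param observed a [spectral_cgc()] result for `ep`.
#' @param ep the (normalized, ROI-level) [epochs()] behind `observed`.
#' @param order state-space model order used for the observed fit.
#' @param n_surr number of surrogates (>= 100; 2000 for full runs).
#' @param alpha null quantile level.
#' @param seed integer seed; surrogate i uses a seed derived from
#'   `(seed, i)` so results do not depend on evaluation order.
#' @param horizon subspace horizon passed to [subspace_identify()].
#' @param store_null keep the full null sample in the result.
#' @return list of class `surrogate_threshold_result`: `thresholded` (a
#'   `cgc_spectrum` with thresholded values), `threshold` (array like
#'   `values`), `n_surr`, `alpha`, `seed`, `redraws`, and optionally
#'   `null` (source x target x freq x n_surr array).
#' @export
surrogate_threshold <- function(observed, ep, order, n_surr = 2000,
                                alpha = 0.05, seed = 1, horizon = NULL,
                                store_null = FALSE) {
  stopifnot(inherits(observed, "cgc_spectrum"), inherits(ep, "epochs"))
  if (n_surr < 100) stopf("n_surr must be >= 100")
  cc <- length(observed$labels)
  nf <- length(observed$freq)
  null <- array(NA_real_, dim = c(cc, cc, nf, n_surr))
  redraws <- 0L
  s <- 0L
  for (i in seq_len(n_surr)) {
    repeat {
      s <- s + 1L
      g <- tryCatch({
        surr <- phase_randomize(ep, seed = derive_seed(seed, s))
        fit <- subspace_identify(surr, order = order, horizon = horizon)
        spectral_cgc(fit, freqs = observed$freq)$values
      }, error = function(e) NULL)
      if (!is.null(g)) break
      redraws <- redraws + 1L
      if (redraws > n_surr) stopf("too many surrogate identification failures")
    }
    null[, , , i] <- g
  }
  if (redraws > 0) warnf("%d surrogate(s) redrawn after identification failure", redraws)
  ## empirical (1 - alpha) order statistic per cell
  ko <- ceiling((1 - alpha) * n_surr)
  thr <- apply(null, c(1, 2, 3), function(v) sort(v)[ko])
  thresholded <- observed
  thresholded$values <- pmax(observed$values - thr, 0)
  out <- list(thresholded = thresholded, threshold = thr, n_surr = n_surr,
              alpha = alpha, seed = seed, redraws = redraws)
  if (store_null) out$null <- null
  class(out) <- "surrogate_threshold_result"
  out
}

#' Permutation test of pre- vs post-condition connectivity changes
#'
#' For each ordered channel pair and frequency band, the observed statistic
#' is the sum over in-band frequencies of the absolute difference between
#' the pre- and post-condition GC spectra. The null is built by randomly
#' reassigning trials to the two conditions and re-running identification
#' and spectral GC on each permuted split (same model order). p-values are
#' exceedance counts divided by `n_perm`; Benjamini-Hochberg FDR is applied
#' across pairs x bands at level `q`; the reported direction is the sign of
#' the post-minus-pre band mean.
#'
#' @param ep_pre,ep_post normalized ROI-level [epochs()] for the two
#'   conditions (same channels, fs, trial length).
#' @param order state-space model order.
#' @param bands a [band_set()]; default [cgc_bands()].
#' @param freqs frequency grid in Hz (default 0-50 by 0.5).
#' @param n_perm number of permutations (>= 100 recommended; 2000 for full
#'   runs).
#' @param q FDR level across pairs x bands.
#' @param horizon subspace horizon in block rows (default
#'   `max(20, 2 * order)`).
#' @param seed integer seed.
#' @return Object of class `edge_change_result`: data frame `table` with
#'   columns `source`, `target`, `band`, `pre`, `post`, `delta`, `stat`,
#'   `p`, `fdr_sig`, `direction`, plus `n_perm`, `q`, `seed`, and the
#'   observed spectra.
#' @export
permutation_prepost <- function(ep_pre, ep_post, order, bands = cgc_bands(),
                                freqs = seq(0, 50, by = 0.5), n_perm = 2000,
                                q = 0.05, horizon = NULL, seed = 1) {
  stopifnot(inherits(ep_pre, "epochs"), inherits(ep_post, "epochs"))
  if (!identical(ep_pre$labels, ep_post$labels)) stopf("channel sets differ")
  if (dim(ep_pre$data)[3] != dim(ep_post$data)[3]) stopf("trial lengths differ")
  n1 <- n_trials(ep_pre); n2 <- n_trials(ep_post)
  if (n1 < 10 || n2 < 10) stopf("need >= 10 trials per condition")
  if (n_perm < 100) warnf("n_perm = %d is low; p-value resolution is coarse", n_perm)
  cc <- dim(ep_pre$data)[2]
  Tn <- dim(ep_pre$data)[3]
  k <- horizon %||% max(20L, 2L * order)
  k <- min(k, (Tn - 1L) %/% 2L)
  fs <- ep_pre$fs
  labels <- ep_pre$labels
  band_idx <- lapply(bands, function(b)
    which(freqs >= b[1] - 1e-9 & freqs <= b[2] + 1e-9))
  if (any(lengths(band_idx) == 0L)) stopf("empty band on this frequency grid")

  gc_from_trials <- function(lams, trials) {
    lam <- pool_lagged_cov(lams, trials)
    fit <- ss_identify_from_lagcov(lam, order = order, k = k, fs = fs,
                                   labels = labels)
    spectral_cgc(fit, freqs = freqs)$values
  }
  band_stat <- function(g1, g2) {
    ## sum over in-band frequencies of |g1 - g2| per ordered pair
    vapply(band_idx, function(idx)
      apply(abs(g1[, , idx, drop = FALSE] - g2[, , idx, drop = FALSE]),
            c(1, 2), sum),
      matrix(0, cc, cc))
  }
  ## per-trial covariances for the combined ensemble; a permutation only
  ## re-pools them
  lam_all <- array(0, dim = c(cc, cc, 2L * k + 1L, n1 + n2))
  lam_all[, , , seq_len(n1)] <- trial_lagged_cov(ep_pre, 2L * k)
  lam_all[, , , n1 + seq_len(n2)] <- trial_lagged_cov(ep_post, 2L * k)

  g_pre <- gc_from_trials(lam_all, seq_len(n1))
  g_post <- gc_from_trials(lam_all, n1 + seq_len(n2))
  obs <- band_stat(g_pre, g_post)              # cc x cc x nbands
  exceed <- array(0, dim = dim(obs))
  failed <- 0L
  with_seed(seed, {
    b <- 0L
    while (b < n_perm) {
      idx1 <- sample.int(n1 + n2, n1)
      stat <- tryCatch({
        gp1 <- gc_from_trials(lam_all, idx1)
        gp2 <- gc_from_trials(lam_all, setdiff(seq_len(n1 + n2), idx1))
        band_stat(gp1, gp2)
      }, error = function(e) NULL)
      if (is.null(stat)) {
        failed <- failed + 1L
        if (failed > n_perm) stopf("too many permutation identification failures")
        next
      }
      b <- b + 1L
      exceed <- exceed + (stat >= obs)
    }
  })
  if (failed > 0) warnf("%d permutation(s) redrawn after identification failure", failed)
  pvals <- exceed / n_perm
  pre_band <- vapply(band_idx, function(idx)
    apply(g_pre[, , idx, drop = FALSE], c(1, 2), mean), matrix(0, cc, cc))
  post_band <- vapply(band_idx, function(idx)
    apply(g_post[, , idx, drop = FALSE], c(1, 2), mean), matrix(0, cc, cc))
  grid <- expand.grid(source = seq_len(cc), target = seq_len(cc),
                      band = seq_along(bands))
  grid <- grid[grid$source != grid$target, ]
  tab <- data.frame(
    source = labels[grid$source], target = labels[grid$target],
    band = names(bands)[grid$band],
    pre = pre_band[cbind(grid$source, grid$target, grid$band)],
    post = post_band[cbind(grid$source, grid$target, grid$band)],
    stat = obs[cbind(grid$source, grid$target, grid$band)],
    p = pvals[cbind(grid$source, grid$target, grid$band)],
    stringsAsFactors = FALSE)
  tab$delta <- tab$post - tab$pre
  fdr <- bh_fdr(tab$p, q = q)
  tab$p_adj <- fdr$adjusted
  tab$fdr_sig <- fdr$reject
  tab$direction <- ifelse(tab$delta > 0, "increase",
                          ifelse(tab$delta < 0, "decrease", "none"))
  structure(list(table = tab, n_perm = n_perm, q = q, seed = seed,
                 labels = labels, bands = bands, freqs = freqs,
                 g_pre = g_pre, g_post = g_post, redraws = failed),
            class = "edge_change_result")
}

#' @export
print.edge_change_result <- function(x, ...) {
  cat(sprintf("Pre/post connectivity permutation test: %d permutations, FDR q = %g\n",
              x$n_perm, x$q))
  sig <- x$table[x$table$fdr_sig, , drop = FALSE]
  if (nrow(sig)) {
    for (i in seq_len(nrow(sig))) {
      cat(sprintf("  %s -> %s [%s]: %s (pre %.4f, post %.4f, p = %.4g)\n",
                  sig$source[i], sig$target[i], sig$band[i], sig$direction[i],
                  sig$pre[i], sig$post[i], sig$p[i]))
    }
  } else cat("  no FDR-significant edge changes\n")
  invisible(x)
}

#' Write an edge-change table as TSV / JSON
#'
#' @param x an `edge_change_result`.
#' @param path output path (`.tsv` or `.json`).
#' @export
write_edge_changes <- function(x, path) {
  stopifnot(inherits(x, "edge_change_result"))
  tab <- x$table[, c("source", "target", "band", "pre", "post", "delta",
                     "p", "fdr_sig", "direction")]
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(tab, path, dataframe = "rows", digits = NA)
  } else {
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
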