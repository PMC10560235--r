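## Shared nonparametric statistics: cluster-based permutation testing,
## Wilcoxon signed rank, Benjamini-Hochberg FDR.

## Welch t statistic per time point for all permutations at once.
## X: (nA + nB) x T data matrix; G: n_perm x n 0/1 membership matrix for
## group "A". Returns an n_perm x T matrix of t values.
welch_t_perms <- function(X, G) {
  n <- nrow(X)
  nA <- rowSums(G)
  nB <- n - nA
  S <- G %*% X                       # group-A sums, n_perm x T
  Q <- G %*% (X^2)
  tot <- matrix(colSums(X), nrow(G), ncol(X), byrow = TRUE)
  tot2 <- matrix(colSums(X^2), nrow(G), ncol(X), byrow = TRUE)
  mA <- S / nA
  mB <- (tot - S) / nB
  vA <- (Q - nA * mA^2) / (nA - 1)
  vB <- (tot2 - Q - nB * mB^2) / (nB - 1)
  (mA - mB) / sqrt(vA / nA + vB / nB)
}

## maximum cluster mass (sum of |t| over a contiguous supra-threshold run)
## for one row of t values
max_cluster_mass <- function(tv, thr) {
  above <- abs(tv) > thr
  if (!any(above)) return(0)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  m <- 0
  for (k in which(r$values)) {
    m <- max(m, sum(abs(tv[starts[k]:ends[k]])))
  }
  m
}

cluster_runs <- function(tv, thr) {
  above <- abs(tv) > thr
  if (!any(above)) {
    return(data.frame(start = integer(), end = integer(), mass = numeric()))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(start = starts[keep], end = ends[keep],
             mass = vapply(keep, function(k)
               sum(abs(tv[starts[k]:ends[k]])), numeric(1)))
}

#' Cluster-based permutation test for two trial ensembles
#'
#' Tests condition differences along time while controlling the family-wise
#' error over time points. A two-sided Welch t statistic is computed per
#' time point and thresholded at `cluster_alpha`; contiguous
#' supra-threshold runs are scored by their summed |t| (cluster mass). The
#' null distribution of the maximum cluster mass is built by randomly
#' permuting condition labels; each observed cluster's p-value is the
#' proportion of null maxima at least as large. Significant clusters
#' shorter than `min_duration` are discarded.
#'
#' @param condA,condB trials x time matrices (same number of columns).
#' @param fs sampling rate in Hz (defines cluster durations).
#' @param n_perm number of permutations (>= 100).
#' @param alpha cluster-level significance threshold.
#' @param cluster_alpha pointwise threshold used to form clusters.
#' @param min_duration minimum cluster duration in seconds (default 0.025).
#' @param seed integer seed for the permutation draw.
#' @param add_one if `TRUE`, use the (count + 1) / (n_perm + 1) p-value
#'   convention; the default counts exceedances divided by `n_perm`.
#' @return Object of class `cluster_result`: data frame `clusters`
#'   (`start_s`, `end_s`, `mass`, `p`, `significant`), the pointwise `t`
#'   trace, `threshold`, `n_perm`, `alpha`, `min_duration`, `seed`.
#' @export
cluster_permutation_test <- function(condA, condB, fs, n_perm = 1000,
                                     alpha = 0.05, cluster_alpha = 0.05,
                                     min_duration = 0.025, seed = 1,
                                     add_one = FALSE) {
  condA <- as.matrix(condA); condB <- as.matrix(condB)
  if (ncol(condA) != ncol(condB)) stopf("condA and condB time axes differ")
  if (nrow(condA) < 2 || nrow(condB) < 2) stopf("need >= 2 trials per condition")
  if (n_perm < 100) stopf("n_perm must be >= 100")
  nA <- nrow(condA); n <- nA + nrow(condB)
  X <- rbind(condA, condB)
  ## pointwise threshold from the Welch df of the observed split
  obs_t <- drop(welch_t_perms(X, matrix(as.numeric(seq_len(n) <= nA), 1, n)))
  dfw <- welch_df(condA, condB)
  thr <- stats::qt(1 - cluster_alpha / 2, dfw)
  obs_clusters <- cluster_runs(obs_t, thr)
  null_max <- with_seed(seed, {
    G <- matrix(0, n_perm, n)
    for (b in seq_len(n_perm)) G[b, sample.int(n, nA)] <- 1
    Tm <- welch_t_perms(X, G)
    apply(Tm, 1, max_cluster_mass, thr = thr)
  })
  denom <- if (add_one) n_perm + 1 else n_perm
  extra <- if (add_one) 1 else 0
  p <- vapply(obs_clusters$mass,
              function(m) (sum(null_max >= m) + extra) / denom, numeric(1))
  dur <- (obs_clusters$end - obs_clusters$start + 1L) / fs
  res <- data.frame(start_s = (obs_clusters$start - 1L) / fs,
                    end_s = obs_clusters$end / fs,
                    duration_s = dur, mass = obs_clusters$mass, p = p,
                    significant = p < alpha & dur >= min_duration)
  structure(list(clusters = res, t = obs_t, threshold = thr,
                 n_perm = n_perm, alpha = alpha,
                 min_duration = min_duration, fs = fs, seed = seed),
            class = "cluster_result")
}

## pooled Welch degrees of freedom (median over time points)
welch_df <- function(A, B) {
  vA <- apply(A, 2, stats::var); vB <- apply(B, 2, stats::var)
  nA <- nrow(A); nB <- nrow(B)
  df <- (vA / nA + vB / nB)^2 /
    ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
  stats::median(df, na.rm = TRUE)
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Cluster permutation test: %d permutations, |t| > %.3f\n",
              x$n_perm, x$threshold))
  sig <- x$clusters[x$clusters$significant, , drop = FALSE]
  if (nrow(sig)) {
    for (i in seq_len(nrow(sig))) {
      cat(sprintf("  cluster %g-%g s, mass %.1f, p = %.4g\n",
                  sig$start_s[i], sig$end_s[i], sig$mass[i], sig$p[i]))
    }
  } else cat("  no significant clusters\n")
  invisible(x)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Exact two-sided p-value from the signed-rank null distribution for
#' n <= `exact_max` untied nonzero differences; otherwise the normal
#' approximation with continuity and tie corrections. Zero differences are
#' dropped.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param exact_max largest n for which the exact distribution is used
#'   (default 25).
#' @return list with `statistic` (W, the positive-rank sum), `z` (normal
#'   approximation, `NA` in the exact case), `p`, `n` (nonzero pairs),
#'   `method`.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max = 25L) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stopf("degenerate input: all differences are zero")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ties <- any(duplicated(r))
  if (n <= exact_max && !ties) {
    ## two-sided exact p from the signed-rank distribution
    p_lo <- stats::psignrank(W, n)
    p_hi <- stats::psignrank(W - 1, n, lower.tail = FALSE)
    p <- min(1, 2 * min(p_lo, p_hi))
    return(list(statistic = W, z = NA_real_, p = p, n = n,
                method = "exact"))
  }
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(statistic = W, z = z, p = p, n = n,
       method = "normal approximation")
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure: with ordered p-values `p(1) <= ... <= p(m)`, rejects
#' hypotheses `1..k*` where `k*` is the largest `k` with
#' `p(k) <= k q / m`. Adjusted p-values are the standard BH adjustment.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return list with `reject` (logical), `adjusted` (BH-adjusted p-values),
#'   `q`.
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (!length(pvals)) {
    return(list(reject = logical(), adjusted = numeric(), q = q))
  }
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stopf("p-values must lie in [0, 1]")
  }
  adjusted <- stats::p.adjust(pvals, method = "BH")
  list(reject = adjusted <= q, adjusted = adjusted, q = q)
}
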