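#' Weighted-degree hub strength
#'
#' Hub strength of a node is the sum of its bidirectional (inflow plus
#' outflow) edge weights in a directed weighted connectivity matrix. The
#' hub statistic contrasts a target node against the median hub strength of
#' the comparison nodes.
#'
#' @param mat square node x node weight matrix (e.g. a band-aggregated GC
#'   matrix from [band_cgc()]); the diagonal is ignored.
#' @param target target node (label or index).
#' @param others comparison nodes (labels or indices); default all
#'   non-target nodes.
#' @return list with `hs` (named hub-strength vector), `statistic`
#'   (`hs[target] - median(hs[others])`), `target`, `others`.
#' @export
weighted_degree <- function(mat, target, others = NULL) {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) stopf("matrix must be square")
  nn <- nrow(mat)
  labels <- rownames(mat) %||% paste0("node", seq_len(nn))
  diag(mat) <- 0
  if (is.character(target)) target <- match(target, labels)
  others <- others %||% setdiff(seq_len(nn), target)
  if (is.character(others)) others <- match(others, labels)
  if (anyNA(c(target, others))) stopf("unknown node label")
  hs <- rowSums(mat) + colSums(mat)
  names(hs) <- labels
  list(hs = hs, statistic = unname(hs[target] - stats::median(hs[others])),
       target = labels[target], others = labels[others])
}

## fast median over the rows of `m` restricted to index set `idx`
row_subset_median <- function(m, idx) {
  sub <- m[idx, , drop = FALSE]
  if (length(idx) == 4L) {
    ## median of 4 = (sum - min - max) / 2, fully vectorized
    (colSums(sub) - apply(sub, 2, max) - apply(sub, 2, min)) / 2
  } else {
    apply(sub, 2, stats::median)
  }
}

#' Edge-permutation hub test
#'
#' Tests whether the target node's hub strength exceeds the median hub
#' strength of the comparison nodes against an empirical null obtained by
#' edge-swapping surrogates: each surrogate randomly permutes the
#' off-diagonal directed edge weights over the off-diagonal positions
#' (preserving the weight multiset exactly). The one-sided p-value is the
#' number of surrogate statistics at least as large as the observed one,
#' divided by the number of surrogates.
#'
#' @inheritParams weighted_degree
#' @param n_swaps number of surrogates (>= 1000; 100000 for full runs).
#' @param seed integer seed.
#' @return Object of class `hub_test_result`: `hs`, `statistic`, `p`,
#'   `n_swaps`, `seed`, `degenerate` flag (all weights equal).
#' @export
hub_test <- function(mat, target, others = NULL, n_swaps = 1e5, seed = 1) {
  if (n_swaps < 1000) stopf("n_swaps must be >= 1000")
  obs <- weighted_degree(mat, target, others)
  mat <- as.matrix(mat)
  nn <- nrow(mat)
  labels <- rownames(mat) %||% paste0("node", seq_len(nn))
  diag(mat) <- 0
  off <- which(row(mat) != col(mat))
  w <- mat[off]
  degenerate <- diff(range(w)) < .Machine$double.eps^0.5
  if (degenerate) {
    warnf("all edge weights equal; hub test is degenerate (p = 1)")
    return(structure(list(hs = obs$hs, statistic = obs$statistic, p = 1,
                          n_swaps = as.integer(n_swaps), seed = seed,
                          degenerate = TRUE, target = obs$target,
                          others = obs$others),
                     class = "hub_test_result"))
  }
  ## incidence matrix: HS = B %*% w for any assignment of weights to
  ## off-diagonal positions
  B <- matrix(0, nn, length(off))
  ri <- row(mat)[off]; ci <- col(mat)[off]
  for (e in seq_along(off)) {
    B[ri[e], e] <- B[ri[e], e] + 1
    B[ci[e], e] <- B[ci[e], e] + 1
  }
  ti <- match(obs$target, labels)
  oi <- match(obs$others, labels)
  n_swaps <- as.integer(n_swaps)
  stat_null <- with_seed(seed, {
    chunk <- 10000L
    res <- numeric(n_swaps)
    done <- 0L
    ne <- length(w)
    while (done < n_swaps) {
      nb <- min(chunk, n_swaps - done)
      Wm <- matrix(0, ne, nb)
      for (b in seq_len(nb)) Wm[, b] <- w[sample.int(ne)]
      HS <- B %*% Wm
      res[done + seq_len(nb)] <- HS[ti, ] - row_subset_median(HS, oi)
      done <- done + nb
    }
    res
  })
  p <- sum(stat_null >= obs$statistic) / n_swaps
  structure(list(hs = obs$hs, statistic = obs$statistic, p = p,
                 n_swaps = n_swaps, seed = seed, degenerate = FALSE,
                 target = obs$target, others = obs$others),
            class = "hub_test_result")
}

#' @export
print.hub_test_result <- function(x, ...) {
  cat(sprintf("Hub test: HS(%s) - median(HS of %s)\n", x$target,
              paste(x$others, collapse = ", ")))
  cat(sprintf("  statistic = %.4f, p = %.4g (%d edge-permutation surrogates)\n",
              x$statistic, x$p, x$n_swaps))
  invisible(x)
}

#' Hub test across frequency bands with FDR correction
#'
#' Runs [hub_test()] on each band slice of a band-aggregated connectivity
#' array and corrects the band p-values with Benjamini-Hochberg FDR.
#'
#' @param band_mats node x node x band array (see [band_cgc()]).
#' @inheritParams hub_test
#' @param q FDR level across bands.
#' @return Object of class `hubness_result`: data frame `table`
#'   (`band`, `statistic`, `p`, `p_adj`, `significant`), the per-band
#'   hub-strength matrix `hs`, `n_swaps`, `q`, `seed`.
#' @export
hub_test_bands <- function(band_mats, target, others = NULL, n_swaps = 1e5,
                           q = 0.05, seed = 1) {
  if (length(dim(band_mats)) != 3L) stopf("band_mats must be node x node x band")
  bands <- dimnames(band_mats)[[3]] %||% paste0("band", seq_len(dim(band_mats)[3]))
  tests <- lapply(seq_along(bands), function(k) {
    hub_test(band_mats[, , k], target, others, n_swaps = n_swaps,
             seed = derive_seed(seed, k))
  })
  pv <- vapply(tests, `[[`, numeric(1), "p")
  fdr <- bh_fdr(pv, q = q)
  tab <- data.frame(band = bands,
                    statistic = vapply(tests, `[[`, numeric(1), "statistic"),
                    p = pv, p_adj = fdr$adjusted,
                    significant = fdr$reject, stringsAsFactors = FALSE)
  hs <- vapply(tests, `[[`, numeric(length(tests[[1]]$hs)), "hs")
  colnames(hs) <- bands
  structure(list(table = tab, hs = hs, n_swaps = as.integer(n_swaps), q = q,
                 seed = seed),
            class = "hubness_result")
}

#' @export
print.hubness_result <- function(x, ...) {
  cat(sprintf("Hub test across %d bands (%d surrogates, FDR q = %g):\n",
              nrow(x$table), x$n_swaps, x$q))
  print(x$table, row.names = FALSE)
  invisible(x)
}
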