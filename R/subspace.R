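## Covariance-driven canonical-variate (CVA) subspace identification from
## trial ensembles. Trials are handled as independent realizations: lagged
## covariances are estimated within each trial (no cross-trial wraparound)
## and pooled, then the block-Hankel covariance between past and future is
## whitened by the past/future block-Toeplitz factors and decomposed by SVD.
## The singular values are the canonical correlations between past and
## future (cosines of the principal angles between the subspaces).

## Per-trial lagged covariance sequences: array c x c x (maxlag+1) x trials
## with lam[, , l+1, i] = (1/T) sum_t y_{t+l} y_t' for trial i. The 1/T
## (rather than 1/(T-l)) normalization keeps each trial's sequence positive
## semidefinite, so pooled sequences are valid covariance models.
trial_lagged_cov <- function(ep, maxlag) {
  d <- dim(ep$data)
  nt <- d[1]; cc <- d[2]; Tn <- d[3]
  if (maxlag >= Tn) stopf("maxlag %d >= trial length %d", maxlag, Tn)
  out <- array(0, dim = c(cc, cc, maxlag + 1L, nt))
  for (i in seq_len(nt)) {
    Y <- matrix(ep$data[i, , ], nrow = cc)
    for (l in 0:maxlag) {
      out[, , l + 1L, i] <-
        tcrossprod(Y[, (1L + l):Tn, drop = FALSE],
                   Y[, 1L:(Tn - l), drop = FALSE]) / Tn
    }
  }
  out
}

pool_lagged_cov <- function(lams, trials = NULL) {
  if (is.null(trials)) trials <- seq_len(dim(lams)[4])
  if (length(trials) == 1L) return(lams[, , , trials, drop = TRUE])
  d <- dim(lams)
  out <- array(0, dim = d[1:3])
  for (i in trials) out <- out + lams[, , , i]
  out / length(trials)
}

## block-Hankel (future x past covariance) and block-Toeplitz (past, future
## autocovariance) matrices from a pooled lag sequence lam[, , l+1] =
## Lambda_l. Assembled by a single vectorized gather through memoized index
## maps (these builds sit inside the surrogate/permutation hot loops).
cov_block_index_cache <- new.env(parent = emptyenv())

cov_block_indices <- function(cc, k) {
  key <- paste(cc, k, sep = "x")
  cached <- cov_block_index_cache[[key]]
  if (!is.null(cached)) return(cached)
  n <- k * cc
  a <- (ceiling(seq_len(n) / cc) - 1L)          # block row (0-based), per row
  i <- seq_len(n) - a * cc                      # within-block row
  A <- matrix(a, n, n); I <- matrix(i, n, n)
  B <- t(A); J <- t(I)
  ## element (r, c) of Lambda_l lives at flat index i + (j-1) cc + l cc^2
  flat <- function(l, i, j, transpose) {
    ifelse(transpose, j + (i - 1L) * cc + l * cc * cc,
           i + (j - 1L) * cc + l * cc * cc)
  }
  H_idx <- flat(A + B + 1L, I, J, matrix(FALSE, n, n))
  lag_p <- B - A
  Tp_idx <- flat(abs(lag_p), I, J, lag_p < 0L)
  lag_f <- A - B
  Tf_idx <- flat(abs(lag_f), I, J, lag_f < 0L)
  lag_s <- B - A + 1L
  Tshift_idx <- flat(abs(lag_s), I, J, lag_s < 0L)
  cached <- list(H = H_idx, Tp = Tp_idx, Tf = Tf_idx, Tshift = Tshift_idx)
  cov_block_index_cache[[key]] <- cached
  cached
}

build_cov_blocks <- function(lam, k) {
  cc <- dim(lam)[1]
  idx <- cov_block_indices(cc, k)
  v <- as.vector(lam)
  n <- k * cc
  list(H = matrix(v[idx$H], n, n),
       Tp = matrix(v[idx$Tp], n, n),
       Tf = matrix(v[idx$Tf], n, n))
}

chol_lower <- function(M) {
  M <- (M + t(M)) / 2
  jit <- 0
  for (i in 0:6) {
    L <- tryCatch(t(chol(M + diag(jit, nrow(M)))), error = function(e) NULL)
    if (!is.null(L)) return(L)
    jit <- max(jit * 10, 1e-10 * mean(diag(M)))
  }
  stopf("covariance block is numerically singular")
}

## CVA core: whitened Hankel SVD from a pooled lag-covariance sequence.
cva_decompose <- function(lam, k) {
  blocks <- build_cov_blocks(lam, k)
  Lf <- chol_lower(blocks$Tf)
  Lp <- chol_lower(blocks$Tp)
  W <- forwardsolve(Lf, blocks$H)
  W <- t(forwardsolve(Lp, t(W)))
  sv <- svd(W)
  sv$d <- pmin(sv$d, 1)
  list(svd = sv, Lf = Lf, Lp = Lp)
}

## Shifted block-Toeplitz E[p_{t+1} p_t'] with blocks
## (a, b) = Lambda_{b - a + 1} (transposed for negative lags).
build_shifted_toeplitz <- function(lam, k) {
  cc <- dim(lam)[1]
  idx <- cov_block_indices(cc, k)
  n <- k * cc
  matrix(as.vector(lam)[idx$Tshift], n, n)
}

## identification given pooled lag covariances (used directly by the
## permutation machinery so per-permutation work is only covariance
## pooling). The CVA state filter J maps the whitened past onto the state
## estimate (state covariance = diag of canonical correlations); A, C, K,
## Sigma then follow from covariance regressions, all expressible in the
## pooled lag covariances.
ss_identify_from_lagcov <- function(lam, order, k, fs, labels) {
  cc <- dim(lam)[1]
  if (order < 1) stopf("order must be >= 1")
  if (order > (k - 1L) * cc) stopf("order %d too large for horizon %d", order, k)
  dec <- cva_decompose(lam, k)
  sv <- dec$svd
  s <- sv$d[seq_len(order)]
  if (s[order] < 1e-12) {
    stopf("rank-deficient past/future covariance: canonical correlation %d is %.3g",
          order, s[order])
  }
  ## state filter: x_t = J p_t with J = S^{1/2} V' Lp^{-1}; then
  ## Cov(x) = S (diagonal)
  Vm <- sv$v[, seq_len(order), drop = FALSE]
  J <- sqrt(s) * t(backsolve(t(dec$Lp), Vm))
  Tp1 <- build_shifted_toeplitz(lam, k)
  ## the CVA state estimate x_{t+1} = J p_t predicts the future from t+1,
  ## so the observation regression targets y_{t+1}:
  ## E[y_{t+1} p_t'] = (Lambda_1, Lambda_2, ..., Lambda_k)
  yrow <- matrix(0, cc, k * cc)
  for (b in seq_len(k)) {
    yrow[, (b - 1L) * cc + seq_len(cc)] <- lam[, , b + 1L]
  }
  ## E[p_{t+1} y_{t+1}'] = (Lambda_0; Lambda_1'; ...; Lambda_{k-1}')
  cvec <- matrix(0, k * cc, cc)
  cvec[seq_len(cc), ] <- lam[, , 1]
  for (a in 2:k) {
    cvec[(a - 1L) * cc + seq_len(cc), ] <- t(lam[, , a])
  }
  sinv <- 1 / s
  Sx1x <- J %*% Tp1 %*% t(J)          # Cov(x_{t+1}, x_t)
  Syx <- yrow %*% t(J)                # Cov(y_t, x_t)
  A <- Sx1x * rep(sinv, each = order)
  C <- Syx * rep(sinv, each = cc)
  rho <- spectral_radius(A)
  if (rho >= 0.999) {
    A <- A * (0.995 / rho)
  }
  L0 <- (lam[, , 1] + t(lam[, , 1])) / 2
  Sig <- L0 - C %*% t(Syx)
  Sig <- (Sig + t(Sig)) / 2
  ev <- eigen(Sig, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) Sig <- Sig + diag(1e-8 * mean(diag(L0)) - min(ev), cc)
  Sx1y <- J %*% cvec                  # Cov(x_{t+1}, y_t)
  K <- t(solve(Sig, t(Sx1y - A %*% (s * t(C)))))
  ## enforce minimum phase (invertibility of the innovations filter)
  for (i in 1:30) {
    if (spectral_radius(A - K %*% C) < 0.999) break
    K <- K * 0.92
  }
  model <- ss_model(A, C, K, Sig, fs = fs, labels = labels, check = FALSE)
  model$canonical_correlations <- sv$d
  model
}

#' Identify an innovations-form state-space model by the subspace method
#'
#' Canonical-variate-weighted (CVA) stochastic subspace identification from
#' a trial ensemble. Lagged covariances are estimated within trials (no
#' cross-trial wraparound) and pooled; the past/future block-Hankel
#' covariance is whitened by the Cholesky factors of the past and future
#' block-Toeplitz covariances and decomposed by SVD; the leading `order`
#' canonical directions define the state filter (state estimate as a linear
#' function of the whitened past), and `A`, `C`, the steady-state Kalman
#' gain `K` and the innovations covariance `Sigma` follow from covariance
#' regressions on the state sequence, all expressed in the pooled lag
#' covariances. Stability of `A` and invertibility of the innovations
#' filter are enforced by projection when estimates land outside the
#' admissible region.
#'
#' @param ep an [epochs()] object (ROI-level, typically ensemble-normalized
#'   by [normalize_trials_for_cgc()]).
#' @param order model order m (state dimension), e.g. from [select_order()].
#' @param horizon past/future horizon in block rows; default
#'   `max(20, 2 * order)` capped by the trial length.
#' @return An [ss_model()] with an extra `canonical_correlations` field.
#' @export
subspace_identify <- function(ep, order, horizon = NULL) {
  stopifnot(inherits(ep, "epochs"))
  Tn <- dim(ep$data)[3]
  k <- horizon %||% max(20L, 2L * order)
  k <- min(k, (Tn - 1L) %/% 2L)
  if (k < 2L) stopf("trials too short for subspace identification")
  lam <- pool_lagged_cov(trial_lagged_cov(ep, 2L * k))
  ss_identify_from_lagcov(lam, order = order, k = k, fs = ep$fs,
                          labels = ep$labels)
}

#' Select the state-space model order from principal angles
#'
#' The model order is the number of principal angles between the past and
#' future data subspaces that are significantly smaller than pi/2,
#' equivalently the number of past/future canonical correlations
#' significantly above zero. Significance is calibrated by a surrogate
#' distribution: the pairing between past and future blocks is shuffled
#' across trials/time, destroying temporal dependence while preserving the
#' marginal structure, and the observed correlations are compared with the
#' `1 - alpha` quantile of the surrogate maximum canonical correlation.
#'
#' @param ep an [epochs()] object.
#' @param max_order cap on the returned order.
#' @param horizon past/future horizon in block rows (default 20).
#' @param alpha significance level of the surrogate threshold.
#' @param n_shuffle number of shuffle surrogates.
#' @param seed integer seed.
#' @return list with `order`, the canonical `correlations`, the surrogate
#'   `threshold`, and the surrogate maxima `null_max`.
#' @export
select_order <- function(ep, max_order = 30L, horizon = 20L, alpha = 0.05,
                         n_shuffle = 20L, seed = 1) {
  stopifnot(inherits(ep, "epochs"))
  d <- dim(ep$data)
  nt <- d[1]; cc <- d[2]; Tn <- d[3]
  k <- min(horizon, (Tn - 1L) %/% 2L)
  ## build explicit past/future data matrices (columns = valid time points
  ## pooled over trials)
  tcols <- k:(Tn - k)
  ncol_tot <- nt * length(tcols)
  Yp <- matrix(0, k * cc, ncol_tot)
  Yf <- matrix(0, k * cc, ncol_tot)
  col <- 0L
  for (i in seq_len(nt)) {
    Y <- matrix(ep$data[i, , ], nrow = cc)
    for (a in seq_len(k)) {
      Yp[(a - 1L) * cc + seq_len(cc), col + seq_along(tcols)] <-
        Y[, tcols - a + 1L, drop = FALSE]
      Yf[(a - 1L) * cc + seq_len(cc), col + seq_along(tcols)] <-
        Y[, tcols + a, drop = FALSE]
    }
    col <- col + length(tcols)
  }
  cancor_from <- function(Yf, Yp) {
    n <- ncol(Yp)
    Lf <- chol_lower(tcrossprod(Yf) / n)
    Lp <- chol_lower(tcrossprod(Yp) / n)
    W <- forwardsolve(Lf, tcrossprod(Yf, Yp) / n)
    W <- t(forwardsolve(Lp, t(W)))
    pmin(svd(W, nu = 0, nv = 0)$d, 1)
  }
  obs <- cancor_from(Yf, Yp)
  null_max <- with_seed(seed, {
    vapply(seq_len(n_shuffle), function(b) {
      cancor_from(Yf[, sample.int(ncol_tot), drop = FALSE], Yp)[1]
    }, numeric(1))
  })
  thr <- stats::quantile(null_max, 1 - alpha, names = FALSE, type = 7)
  m <- sum(obs > thr)
  if (m == 0L) warnf("no significant dynamics detected; order 0")
  list(order = min(m, max_order), correlations = obs, threshold = thr,
       null_max = null_max)
}
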