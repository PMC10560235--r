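#' Innovations-form state-space model
#'
#' Container for the innovations (one-step predictor) form
#' \deqn{x_{t+1} = A x_t + K \epsilon_t}
#' \deqn{y_t = C x_t + \epsilon_t}
#' with latent state dimension `m`, observed channels `c`, steady-state
#' Kalman gain `K` and innovations covariance `Sigma`. Stability requires all
#' eigenvalues of `A` inside the unit circle; the minimum-phase condition
#' requires the same of `A - K C` (so the model can be inverted to recover
#' the innovations from the observations).
#'
#' @param A state transition matrix (m x m).
#' @param C observation matrix (c x m).
#' @param K steady-state Kalman gain (m x c).
#' @param Sigma innovations covariance (c x c, symmetric positive definite).
#' @param fs sampling rate in Hz.
#' @param labels channel (ROI) labels, length c.
#' @param check validate stability / minimum phase / positive definiteness.
#' @return An object of class `ss_model`.
#' @export
ss_model <- function(A, C, K, Sigma, fs, labels = NULL, check = TRUE) {
  A <- as.matrix(A); C <- as.matrix(C); K <- as.matrix(K)
  Sigma <- as.matrix(Sigma)
  m <- nrow(A); cc <- nrow(C)
  if (ncol(A) != m) stopf("A must be square")
  if (ncol(C) != m) stopf("C must be c x m")
  if (!all(dim(K) == c(m, cc))) stopf("K must be m x c")
  if (!all(dim(Sigma) == c(cc, cc))) stopf("Sigma must be c x c")
  labels <- labels %||% paste0("ch", seq_len(cc))
  if (length(labels) != cc) stopf("labels must have length %d", cc)
  Sigma <- (Sigma + t(Sigma)) / 2
  if (check) {
    rA <- spectral_radius(A)
    if (rA >= 1) stopf("unstable model: spectral radius of A is %.4f", rA)
    rM <- spectral_radius(A - K %*% C)
    if (rM >= 1 + 1e-8) {
      stopf("non-minimum-phase model: spectral radius of A - K C is %.4f", rM)
    }
    ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stopf("Sigma is not positive definite")
  }
  structure(list(A = A, C = C, K = K, Sigma = Sigma, m = m, n_channels = cc,
                 fs = fs, labels = labels),
            class = "ss_model")
}

spectral_radius <- function(M) {
  if (nrow(M) == 0L) return(0)
  max(Mod(eigen(M, only.values = TRUE)$values))
}

#' @export
print.ss_model <- function(x, ...) {
  cat(sprintf(
    "Innovations-form state-space model: %d channels, order m = %d, fs = %g Hz\n",
    x$n_channels, x$m, x$fs))
  cat(sprintf("  spectral radius: A %.3f, A - KC %.3f\n",
              spectral_radius(x$A), spectral_radius(x$A - x$K %*% x$C)))
  invisible(x)
}

#' Embed a VAR process as an innovations-form state-space model
#'
#' A stable VAR(p) `y_t = sum_k A_k y_{t-k} + eps_t` is exactly an
#' innovations model with state `x_t = (y_{t-1}, ..., y_{t-p})`,
#' `C = (A_1 ... A_p)`, companion-form transition and gain
#' `K = (I, 0, ..., 0)'`.
#'
#' @param Acoef coefficient array c x c x p.
#' @param Sigma VAR noise covariance (c x c).
#' @param fs sampling rate in Hz.
#' @param labels optional channel labels.
#' @return An `ss_model`.
#' @export
var_to_ss <- function(Acoef, Sigma, fs, labels = NULL) {
  if (length(dim(Acoef)) != 3L) stopf("Acoef must be a c x c x p array")
  cc <- dim(Acoef)[1]; p <- dim(Acoef)[3]
  C <- matrix(Acoef, cc, cc * p)
  A <- rbind(C, cbind(diag(1, cc * (p - 1)),
                      matrix(0, cc * max(p - 1, 0), cc)))
  if (p == 1L) A <- C
  K <- rbind(diag(1, cc), matrix(0, cc * (p - 1), cc))
  ss_model(A, C, K, Sigma, fs = fs, labels = labels)
}

## Fixed-point solver for the stochastic-realization (covariance form)
## discrete algebraic Riccati equation
##   P = A P A' + (Gbar - A P C') (L0 - C P C')^{-1} (Gbar - A P C')'
## where Gbar = E[x_{t+1} y_t'] and L0 = cov(y_t). Returns the steady-state
## Kalman gain K and innovations covariance Sigma of the predictor model.
## Iteration from P = 0 is the Kalman filter Riccati recursion, monotone for
## a positive-real covariance model. `ridge` regularizes L0 when estimated
## covariances are not exactly positive real.
dare_stochastic <- function(A, C, Gbar, L0, tol = 1e-10, max_iter = 1e4,
                            ridge = 0) {
  m <- nrow(A); cc <- nrow(L0)
  if (ridge > 0) L0 <- L0 + diag(ridge, cc)
  At <- t(A); Ct <- t(C)
  run <- function() {
    P <- matrix(0, m, m)
    iter <- 0L; delta <- Inf
    while (iter < max_iter) {
      iter <- iter + 1L
      PCt <- P %*% Ct
      Sig <- L0 - C %*% PCt
      ## chol() errors when the innovations covariance loses positive
      ## definiteness (covariance model not positive real)
      R <- chol((Sig + t(Sig)) / 2)
      KgT <- backsolve(R, forwardsolve(t(R), t(Gbar - A %*% PCt)))
      Pn <- A %*% P %*% At + crossprod(KgT, (Sig %*% KgT))
      Pn <- (Pn + t(Pn)) / 2
      delta <- max(abs(Pn - P)) / max(1, max(abs(Pn)))
      P <- Pn
      if (delta < tol) break
    }
    if (delta >= tol) {
      stopf("DARE did not converge in %d iterations (residual %.3g)",
            as.integer(max_iter), delta)
    }
    PCt <- P %*% Ct
    Sig <- L0 - C %*% PCt
    Sig <- (Sig + t(Sig)) / 2
    Kg <- t(solve(Sig, t(Gbar - A %*% PCt)))
    list(K = Kg, Sigma = Sig, P = P, iterations = iter, ridge = ridge)
  }
  out <- tryCatch(run(), error = function(e) e)
  if (inherits(out, "error")) {
    if (grepl("did not converge", conditionMessage(out))) stop(out)
    ## regularize and retry on positive-definiteness failures
    return(dare_stochastic(A, C, Gbar, L0, tol, max_iter,
                           ridge = max(ridge * 10, 1e-8 * mean(diag(L0)))))
  }
  out
}

## State covariance Pi = A Pi A' + K Sigma K' (discrete Lyapunov) by
## doubling: Pi = sum_k A^k Q (A^k)'.
lyapunov_state_cov <- function(A, Q, tol = 1e-12, max_iter = 200L) {
  P <- Q
  Ak <- A
  for (i in seq_len(max_iter)) {
    incr <- Ak %*% P %*% t(Ak)
    P <- P + incr
    if (max(abs(incr)) < tol * max(1, max(abs(P)))) break
    Ak <- Ak %*% Ak
  }
  (P + t(P)) / 2
}

## Evaluate G(f) = D + Cm (z I - Am)^{-1} Bm on z = exp(2i pi f / fs), for
## all frequencies at once, via eigendecomposition of Am. Returns a complex
## array dim c(nrow(Cm), ncol(Bm), length(freqs)). Falls back to direct
## per-frequency solves when Am is near-defective.
resolvent_transfer <- function(Am, Bm, Cm, D, freqs, fs) {
  nr <- nrow(Cm); nc <- ncol(Bm); nf <- length(freqs)
  z <- exp(2i * pi * freqs / fs)
  out <- array(0i, dim = c(nr, nc, nf))
  m <- nrow(Am)
  if (m == 0L) {
    for (k in seq_len(nf)) out[, , k] <- D
    return(out)
  }
  eg <- tryCatch(eigen(Am), error = function(e) NULL)
  use_eig <- FALSE
  Pinv <- NULL
  if (!is.null(eg)) {
    Pinv <- tryCatch(solve(eg$vectors), error = function(e) NULL)
    if (!is.null(Pinv)) {
      ## cheap 1-norm condition estimate; fall back to direct solves when
      ## the eigenbasis is near-defective
      kap <- max(colSums(Mod(eg$vectors))) * max(colSums(Mod(Pinv)))
      use_eig <- is.finite(kap) && kap < 1e8
    }
  }
  if (use_eig) {
    CP <- Cm %*% eg$vectors          # nr x m
    PB <- Pinv %*% Bm                # m x nc
    ## T[(j-1)*nr + i, l] = CP[i,l] * PB[l,j]
    Tm <- matrix(0i, nr * nc, m)
    for (j in seq_len(nc)) {
      Tm[(j - 1L) * nr + seq_len(nr), ] <- CP * rep(PB[, j], each = nr)
    }
    R <- 1 / (rep(z, each = m) - rep(eg$values, nf))  # m x nf column-major
    dim(R) <- c(m, nf)
    out <- Tm %*% R + as.vector(D)                    # (nr*nc) x nf, D recycled
    dim(out) <- c(nr, nc, nf)
  } else {
    Im <- diag(1, m)
    for (k in seq_len(nf)) {
      out[, , k] <- D + Cm %*% solve(z[k] * Im - Am, Bm)
    }
  }
  out
}

#' Transfer function and cross-spectral density of a state-space model
#'
#' Computes, on a grid of frequencies, the innovations transfer function
#' \eqn{H(f) = C (e^{2\pi i f / fs} I - A)^{-1} K + I} and the cross-spectral
#' density \eqn{S(f) = H(f) \Sigma H(f)^*} (one-sided in frequency, per unit
#' Hz up to a constant factor).
#'
#' @param model an [ss_model()].
#' @param freqs frequency grid in Hz, within `[0, fs/2]`.
#' @return A list of class `spectral_matrices` with elements `freq`, `H`
#'   (complex c x c x nf), `S` (complex Hermitian c x c x nf), `fs`, `labels`.
#' @export
spectral_matrices <- function(model, freqs) {
  stopifnot(inherits(model, "ss_model"))
  if (any(freqs < 0 | freqs > model$fs / 2 + 1e-9)) {
    stopf("freqs must lie in [0, fs/2]")
  }
  cc <- model$n_channels
  H <- resolvent_transfer(model$A, model$K, model$C, diag(1, cc),
                          freqs, model$fs)
  S <- array(0i, dim = dim(H))
  for (k in seq_along(freqs)) {
    Hk <- H[, , k, drop = TRUE]
    if (cc == 1L) Hk <- matrix(Hk, 1, 1)
    Sk <- Hk %*% model$Sigma %*% Conj(t(Hk))
    S[, , k] <- (Sk + Conj(t(Sk))) / 2
  }
  structure(list(freq = freqs, H = H, S = S, fs = model$fs,
                 labels = model$labels),
            class = "spectral_matrices")
}
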