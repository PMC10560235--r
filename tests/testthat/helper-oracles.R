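## Independent oracles used across the suite. These deliberately avoid the
## package's state-space route: VAR quantities are computed from coefficient
## polynomials and autocovariance algebra only.

## random stable VAR(p) with mildly correlated noise; coefficients are
## shrunk until the companion spectral radius is below `rho_max`
random_stable_var <- function(nc, p, seed, rho_max = 0.9) {
  withr::with_seed(seed, {
    Acoef <- array(rnorm(nc * nc * p, sd = 0.4), dim = c(nc, nc, p))
    repeat {
      comp <- rbind(matrix(Acoef, nc, nc * p),
                    cbind(diag(1, nc * (p - 1)), matrix(0, nc * (p - 1), nc)))
      if (p == 1) comp <- matrix(Acoef, nc, nc)
      rho <- max(Mod(eigen(comp, only.values = TRUE)$values))
      if (rho < rho_max) break
      Acoef <- Acoef * 0.93
    }
    L <- diag(nc) + matrix(rnorm(nc * nc, sd = 0.15), nc, nc)
    Sigma <- crossprod(L) / 2 + diag(0.5, nc)
    list(Acoef = Acoef, Sigma = Sigma)
  })
}

## simulate one long realization of a VAR (for regression-based checks)
var_simulate <- function(Acoef, Sigma, n, seed, burn = 500) {
  nc <- dim(Acoef)[1]; p <- dim(Acoef)[3]
  Lc <- t(chol(Sigma))
  withr::with_seed(seed, {
    y <- matrix(0, nc, n + burn)
    for (t in (p + 1):(n + burn)) {
      acc <- Lc %*% rnorm(nc)
      for (k in seq_len(p)) acc <- acc + Acoef[, , k] %*% y[, t - k]
      y[, t] <- acc
    }
    y[, burn + seq_len(n), drop = FALSE]
  })
}

## analytic autocovariance sequence Gamma_0..Gamma_L of a stable VAR via
## the companion-form Lyapunov equation
var_autocov <- function(Acoef, Sigma, L) {
  nc <- dim(Acoef)[1]; p <- dim(Acoef)[3]
  comp <- rbind(matrix(Acoef, nc, nc * p),
                cbind(diag(1, nc * (p - 1)), matrix(0, nc * (p - 1), nc)))
  if (p == 1) comp <- matrix(Acoef, nc, nc)
  Q <- matrix(0, nc * p, nc * p)
  Q[seq_len(nc), seq_len(nc)] <- Sigma
  ## solve P = comp P comp' + Q by doubling
  P <- Q; M <- comp
  for (i in 1:120) {
    inc <- M %*% P %*% t(M)
    P <- P + inc
    if (max(abs(inc)) < 1e-14 * max(abs(P))) break
    M <- M %*% M
  }
  G <- array(0, dim = c(nc, nc, L + 1))
  Pk <- P
  G[, , 1] <- P[seq_len(nc), seq_len(nc)]
  for (l in seq_len(L)) {
    Pk <- comp %*% Pk
    G[, , l + 1] <- Pk[seq_len(nc), seq_len(nc)]
  }
  G
}

## multivariate Levinson-Whittle recursion: fit VAR(p) to an autocovariance
## sequence. Returns forward coefficients and innovation covariance.
whittle_var <- function(G, p) {
  nc <- dim(G)[1]
  A <- array(0, dim = c(nc, nc, p))   # forward
  B <- array(0, dim = c(nc, nc, p))   # backward
  Vf <- G[, , 1]; Vb <- G[, , 1]
  for (n in seq_len(p)) {
    ## prediction error covariance between forward residual and y_{t-n}
    D <- G[, , n + 1]
    if (n > 1) {
      for (k in seq_len(n - 1)) D <- D - A[, , k] %*% G[, , n - k + 1]
    }
    An <- D %*% solve(Vb)
    Bn <- t(D) %*% solve(Vf)
    Anew <- A; Bnew <- B
    Anew[, , n] <- An
    Bnew[, , n] <- Bn
    if (n > 1) {
      for (k in seq_len(n - 1)) {
        Anew[, , k] <- A[, , k] - An %*% B[, , n - k]
        Bnew[, , k] <- B[, , k] - Bn %*% A[, , n - k]
      }
    }
    A <- Anew; B <- Bnew
    Vf_new <- Vf - An %*% Vb %*% t(An)
    Vb <- Vb - Bn %*% Vf %*% t(Bn)
    Vf <- Vf_new
  }
  list(Acoef = A, Sigma = (Vf + t(Vf)) / 2)
}

## VAR transfer function H(f) = (I - sum_k A_k z^-k)^{-1}, z = e^{2 pi i f/fs}
var_transfer <- function(Acoef, freqs, fs) {
  nc <- dim(Acoef)[1]; p <- dim(Acoef)[3]
  H <- array(0i, dim = c(nc, nc, length(freqs)))
  for (kf in seq_along(freqs)) {
    z <- exp(-2i * pi * freqs[kf] / fs)
    Phi <- diag(1 + 0i, nc)
    zk <- 1 + 0i
    for (k in seq_len(p)) {
      zk <- zk * z
      Phi <- Phi - Acoef[, , k] * zk
    }
    H[, , kf] <- solve(Phi)
  }
  H
}

## Brute-force Geweke conditional spectral GC for a known VAR:
## full model analytic; reduced model (all channels except the source)
## fitted to the analytic autocovariance sequence by the Whittle recursion
## (high order); spectra from coefficient-polynomial inversion.
oracle_cgc_var <- function(Acoef, Sigma, source, freqs, fs, red_order = 60) {
  nc <- dim(Acoef)[1]
  r <- setdiff(seq_len(nc), source)
  G <- var_autocov(Acoef, Sigma, red_order + 1)
  red <- whittle_var(G[r, r, , drop = FALSE], red_order)
  Hfull <- var_transfer(Acoef, freqs, fs)
  Hred <- var_transfer(red$Acoef, freqs, fs)
  vj <- Sigma[source, source] - Sigma[source, r, drop = FALSE] %*%
    solve(Sigma[r, r, drop = FALSE], Sigma[r, source, drop = FALSE])
  vj <- drop(vj)
  out <- matrix(0, length(r), length(freqs))
  tdom <- log(diag(as.matrix(red$Sigma))) - log(diag(Sigma)[r])
  for (kf in seq_along(freqs)) {
    Hs <- solve(Hred[, , kf], matrix(Hfull[r, , kf], length(r), nc))
    Sii <- Re(rowSums((Hs %*% Sigma) * Conj(Hs)))
    num <- Sii - Mod(Hs[, source])^2 * vj
    out[, kf] <- log(Sii) - log(pmax(num, Sii * 1e-14))
  }
  list(gc = out, targets = r, time_domain = tdom)
}

## exact two-sided Wilcoxon signed-rank p by enumerating all sign patterns
wilcoxon_enum_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Wnull <- as.vector(signs %*% r)
  p_lo <- mean(Wnull <= W)
  p_hi <- mean(Wnull >= W)
  min(1, 2 * min(p_lo, p_hi))
}

## brute-force BH step-up flags: largest k with p_(k) <= k q / m
bh_enum_reject <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  ks <- which(ps <= seq_len(m) * q / m)
  rej <- logical(m)
  if (length(ks)) rej[o[seq_len(max(ks))]] <- TRUE
  rej
}

## small helper: epochs of i.i.d. Gaussian noise
noise_epochs <- function(n_trials, nc, Tn, fs = 100, seed = 1, sd = 1) {
  withr::with_seed(seed, {
    epochs(array(rnorm(n_trials * nc * Tn, sd = sd),
                 dim = c(n_trials, nc, Tn)), fs = fs)
  })
}
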