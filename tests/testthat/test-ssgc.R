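test_that("spectral matrices obey closed forms and Parseval", {
  ## memoryless model: H = I, S = Sigma at every frequency
  Sig <- matrix(c(2, 0.5, 0.5, 1), 2)
  m0 <- ss_model(A = matrix(0, 2, 2), C = diag(0, 2, 2), K = diag(0, 2, 2),
                 Sigma = Sig, fs = 100)
  sm <- spectral_matrices(m0, seq(0, 50, 5))
  for (k in 1:11) {
    expect_equal(Re(sm$H[, , k]), diag(2), tolerance = 1e-12)
    expect_equal(Re(sm$S[, , k]), Sig, tolerance = 1e-12)
  }

  ## univariate AR(1) spectrum sigma^2 / |1 - a e^{-i w}|^2
  a <- 0.7; s2 <- 1.3; fs <- 100
  mod <- var_to_ss(array(a, c(1, 1, 1)), matrix(s2), fs = fs)
  fr <- seq(0, 50, 0.5)
  sm1 <- spectral_matrices(mod, fr)
  truth <- s2 / Mod(1 - a * exp(-2i * pi * fr / fs))^2
  expect_equal(as.vector(Re(sm1$S[1, 1, ])), truth, tolerance = 1e-10)

  ## Parseval: mean of S over [0, fs/2] approximates the process variance
  ## (rectangle rule with endpoint bins, hence the 3% slack)
  expect_lt(abs(mean(truth) - s2 / (1 - a^2)) / (s2 / (1 - a^2)), 0.03)
})

test_that("state-basis changes leave transfer, spectra and GC invariant", {
  s <- random_stable_var(2, 2, seed = 41)
  mod <- var_to_ss(s$Acoef, s$Sigma, fs = 100)
  fr <- seq(0, 50, 2)
  base_S <- spectral_matrices(mod, fr)$S
  base_g <- spectral_cgc(mod, fr)$values
  withr::with_seed(42, {
    for (rep in 1:3) {
      Tm <- matrix(rnorm(16), 4) + diag(4)
      mod2 <- ss_model(solve(Tm, mod$A %*% Tm), mod$C %*% Tm,
                       solve(Tm, mod$K), mod$Sigma, fs = 100)
      expect_equal(spectral_matrices(mod2, fr)$S, base_S, tolerance = 1e-8)
      expect_equal(spectral_cgc(mod2, fr)$values, base_g, tolerance = 1e-6)
    }
  })
})

test_that("GC is nonnegative and zero for independent channels", {
  ## diagonal VAR: no coupling anywhere
  Ac <- array(0, c(3, 3, 1))
  diag(Ac[, , 1]) <- c(0.5, -0.3, 0.7)
  g <- spectral_cgc(var_to_ss(Ac, diag(3), fs = 100))
  v <- g$values[!is.na(g$values)]
  expect_true(all(v >= 0))
  expect_lt(max(v), 1e-6)
})

test_that("subspace identification recovers a known order-4 system", {
  s <- list(Acoef = array(c(1.2, 0.6, 0, 0.9, -0.5, 0, 0, -0.4),
                          c(2, 2, 2)),
            Sigma = diag(c(1, 0.8)))
  mod <- var_to_ss(s$Acoef, s$Sigma, fs = 100)
  withr::with_seed(43, {
    dat <- array(0, c(80, 2, 250))
    for (i in 1:80) dat[i, , ] <- var_simulate(s$Acoef, s$Sigma, 250,
                                               seed = sample.int(1e6, 1))
  })
  ep <- epochs(dat, fs = 100)
  fit <- subspace_identify(ep, order = 4)
  fr <- seq(0, 50, 0.5)
  Ht <- spectral_matrices(mod, fr)$H
  Hh <- spectral_matrices(fit, fr)$H
  relerr <- sqrt(sum(Mod(Hh - Ht)^2) / sum(Mod(Ht)^2))
  expect_lt(relerr, 0.05)
  ## identified model is stable and minimum phase
  expect_lt(max(Mod(eigen(fit$A)$values)), 1)
  expect_lt(max(Mod(eigen(fit$A - fit$K %*% fit$C)$values)), 1)
})

test_that("white noise identifies as (near) memoryless and order 0", {
  ep <- noise_epochs(30, 2, 200, seed = 44)
  fit <- subspace_identify(ep, order = 2)
  sm <- spectral_matrices(fit, seq(0, 50, 5))
  for (k in seq_along(sm$freq)) {
    expect_lt(max(Mod(sm$H[, , k] - diag(2))), 0.15)
  }
  sel <- suppressWarnings(select_order(ep, max_order = 10, seed = 3))
  expect_equal(sel$order, 0L)
})

test_that("order selection recovers the true order of a simple system", {
  s <- list(Acoef = array(c(1.2, 0.6, 0, 0.9, -0.5, 0, 0, -0.4),
                          c(2, 2, 2)),
            Sigma = diag(c(1, 0.8)))
  hits <- 0
  for (sd_ in 1:10) {
    withr::with_seed(450 + sd_, {
      dat <- array(0, c(100, 2, 300))
      for (i in 1:100) dat[i, , ] <- var_simulate(s$Acoef, s$Sigma, 300,
                                                  seed = sample.int(1e6, 1))
    })
    sel <- select_order(epochs(dat, fs = 100), max_order = 12,
                        n_shuffle = 30, seed = sd_)
    hits <- hits + (sel$order == 4L)
  }
  expect_gte(hits, 9)
})

test_that("state-space GC matches the VAR regression oracle", {
  ## one bivariate system checked densely here; the acceptance suite runs
  ## the full randomized battery
  s <- random_stable_var(2, 3, seed = 46)
  fr <- seq(0, 50, 0.5)
  g <- spectral_cgc(var_to_ss(s$Acoef, s$Sigma, fs = 100), fr)
  for (src in 1:2) {
    o <- oracle_cgc_var(s$Acoef, s$Sigma, src, fr, 100)
    tgt <- o$targets[1]
    denom <- sqrt(sum(o$gc[1, ]^2))
    if (denom > 1e-8) {
      expect_lt(sqrt(sum((g$values[src, tgt, ] - o$gc[1, ])^2)) / denom, 0.02)
    }
    expect_equal(g$time_domain[src, tgt], o$time_domain[1], tolerance = 1e-6)
  }
})

test_that("chain systems show vanishing conditional GC on the indirect link", {
  ## 1 -> 2 -> 3 with no direct 1 -> 3 coupling
  Ac <- array(0, c(3, 3, 1))
  diag(Ac[, , 1]) <- c(0.5, 0.4, 0.3)
  Ac[2, 1, 1] <- 0.6
  Ac[3, 2, 1] <- 0.6
  mod <- var_to_ss(Ac, diag(3), fs = 100)
  fr <- seq(0, 50, 1)
  g <- spectral_cgc(mod, fr)
  ## conditional GC 1 -> 3 given 2 vanishes
  expect_lt(max(g$values[1, 3, ]), 1e-8)
  ## but the pairwise (unconditioned) influence 1 -> 3 is present: drop
  ## channel 2 from the model via its marginal VAR fitted from autocovs
  G <- var_autocov(Ac, diag(3), 41)
  marg <- whittle_var(G[c(1, 3), c(1, 3), , drop = FALSE], 40)
  gm <- spectral_cgc(var_to_ss(marg$Acoef, marg$Sigma, fs = 100), fr)
  expect_gt(max(gm$values[1, 2, ]), 0.05)
})

test_that("band aggregation of GC spectra", {
  s <- random_stable_var(2, 1, seed = 47)
  g <- spectral_cgc(var_to_ss(s$Acoef, s$Sigma, fs = 100))
  ## flat spectrum -> every band equals the constant
  gflat <- g
  gflat$values[1, 2, ] <- 0.3
  b <- band_cgc(gflat)
  expect_true(all(abs(b[1, 2, ] - 0.3) < 1e-12))
  expect_error(band_cgc(g, band_set(list(hf = c(60, 80)))), "no frequency")
  ## frequency grid tops out at 50 Hz by default
  expect_equal(max(g$freq), 50)
})
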