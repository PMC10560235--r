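test_that("phase randomization preserves per-channel spectra exactly", {
  ep <- noise_epochs(5, 3, 128, seed = 51)
  surr <- phase_randomize(ep, seed = 52)
  for (i in 1:5) for (ch in 1:3) {
    p0 <- Mod(fft(ep$data[i, ch, ]))^2
    p1 <- Mod(fft(surr$data[i, ch, ]))^2
    expect_lt(max(abs(p1 - p0)) / max(p0), 1e-10)
  }
  ## total power (Parseval) preserved
  expect_equal(sum(surr$data^2), sum(ep$data^2), tolerance = 1e-10)
  ## constant signal is unchanged (all energy at DC)
  cst <- epochs(array(4, c(2, 1, 64)), fs = 100)
  expect_equal(phase_randomize(cst, seed = 1)$data, cst$data,
               tolerance = 1e-12)
  ## odd-length epochs are handled too
  odd <- noise_epochs(2, 1, 65, seed = 53)
  so <- phase_randomize(odd, seed = 3)
  expect_lt(max(abs(Mod(fft(so$data[1, 1, ])) - Mod(fft(odd$data[1, 1, ])))),
            1e-8)
})

test_that("phase randomization destroys cross-channel correlation", {
  withr::with_seed(54, {
    n <- 512
    base <- matrix(0, 10, n)
    dat <- array(0, c(10, 2, n))
    for (i in 1:10) {
      x <- rnorm(n)
      dat[i, 1, ] <- x
      dat[i, 2, ] <- x           # perfectly correlated channels
    }
  })
  ep <- epochs(dat, fs = 100)
  rs <- vapply(1:10, function(i) {
    surr <- phase_randomize(ep, seed = 100 + i)
    abs(cor(surr$data[1, 1, ], surr$data[1, 2, ]))
  }, numeric(1))
  expect_lt(median(rs), 3 / sqrt(512))
})

test_that("surrogate thresholding isolates a planted band-limited edge", {
  spec <- network_spec(3, f0 = c(10, 25, 40), damping = 0.75,
                       couplings = data.frame(source = 3, target = 1,
                                              gain = 0.4, lag = 1,
                                              band_low = 31, band_high = 50),
                       noise_sd = 1, fs = 100)
  ep <- normalize_trials_for_cgc(
    simulate_network_trials(spec, NULL, 60, 200, seed = 6))
  fit <- subspace_identify(ep, order = 8, horizon = 20)
  obs <- spectral_cgc(fit)
  st <- surrogate_threshold(obs, ep, order = 8, n_surr = 200, alpha = 0.05,
                            seed = 10, horizon = 20)
  v <- st$thresholded$values
  gi <- which(obs$freq >= 31 & obs$freq <= 50)
  expect_gt(mean(v[3, 1, gi]), 0.2)
  mask <- array(TRUE, dim(v))
  for (i in 1:3) mask[i, i, ] <- FALSE
  mask[3, 1, ] <- FALSE
  expect_lte(mean(v[mask] > 0), 0.05)
  ## null sample size contract
  st2 <- surrogate_threshold(obs, ep, order = 8, n_surr = 100, seed = 2,
                             horizon = 20, store_null = TRUE)
  expect_equal(dim(st2$null)[4], 100L)
  expect_true(all(st2$null >= 0, na.rm = TRUE))
  ## monotone in the observed spectrum
  obs_hi <- obs
  obs_hi$values <- obs$values + 0.1
  st3 <- surrogate_threshold(obs_hi, ep, order = 8, n_surr = 100, seed = 2,
                             horizon = 20)
  expect_true(all(st3$thresholded$values >= st2$thresholded$values - 1e-12,
                  na.rm = TRUE))
})

test_that("pre/post permutation is label-symmetric", {
  spec <- example_network_spec()
  pre <- normalize_trials_for_cgc(
    simulate_network_trials(spec, "pre", 30, 200, seed = 55))
  post <- normalize_trials_for_cgc(
    simulate_network_trials(spec, "post", 30, 200, seed = 56))
  r1 <- permutation_prepost(pre, post, order = 10, horizon = 20,
                            n_perm = 100, seed = 7)
  r2 <- permutation_prepost(post, pre, order = 10, horizon = 20,
                            n_perm = 100, seed = 7)
  ## statistic is |difference|-based: same observed stat, hence same p
  ## up to permutation-sampling noise with identical derived seeds
  expect_equal(r1$table$stat, r2$table$stat, tolerance = 1e-10)
  ## p-values agree up to permutation Monte-Carlo noise
  expect_lt(max(abs(r1$table$p - r2$table$p)), 0.3)
  ## signs flip
  expect_equal(r1$table$delta, -r2$table$delta, tolerance = 1e-10)
})
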