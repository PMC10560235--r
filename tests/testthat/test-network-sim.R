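test_that("network specifications validate stability and coupling fields", {
  expect_error(network_spec(2, damping = 1.2), "damping")
  expect_error(network_spec(2, couplings = data.frame(
    source = 1, target = 2, gain = 0.5, lag = 0, band_low = 4,
    band_high = 8)), "lag")
  ## strong self-reinforcing loop -> unstable companion root, named
  expect_error(network_spec(2, f0 = 10, damping = 0.99, couplings =
    data.frame(source = c(1, 2), target = c(2, 1), gain = c(3, 3),
               lag = c(1, 1), band_low = 8, band_high = 12)),
    "unstable network.*modulus")
})

test_that("uncoupled nodes give uncorrelated trials and zero theoretical GC", {
  spec <- network_spec(2, f0 = c(10, 25), damping = 0.7, noise_sd = 1,
                       fs = 100)
  ep <- simulate_network_trials(spec, NULL, n_trials = 4, n_samples = 5000,
                                seed = 2)
  for (i in 1:4) {
    x <- ep$data[i, 1, ]; y <- ep$data[i, 2, ]
    for (l in c(0, 1, 5)) {
      N <- length(x) - l
      r <- cor(x[(1 + l):length(x)], y[seq_len(N)])
      expect_lt(abs(r), 3 / sqrt(N))
    }
  }
  g <- spectral_cgc(network_ss(spec), freqs = seq(0, 50, 1))
  expect_true(all(g$values[1, 2, ] <= 1e-6))
  expect_true(all(g$values[2, 1, ] <= 1e-6))
})

test_that("simulated trials carry the generator coefficients", {
  ## single-lag coupling 1 -> 2; a long-sample least-squares VAR fit must
  ## recover the planted coefficient
  spec <- network_spec(2, f0 = c(10, 20), damping = 0.6,
                       couplings = data.frame(source = 1, target = 2,
                                              gain = 0.5, lag = 2,
                                              band_low = 9, band_high = 11),
                       noise_sd = 1, fs = 100)
  truth <- network_var(spec)$Acoef
  ep <- simulate_network_trials(spec, NULL, n_trials = 1, n_samples = 1e5,
                                seed = 4)
  y <- matrix(ep$data[1, , ], nrow = 2)
  p <- dim(truth)[3]
  n <- ncol(y)
  X <- NULL
  for (k in seq_len(p)) X <- cbind(X, t(y[, (p - k + 1):(n - k)]))
  Y <- t(y[, (p + 1):n])
  beta <- qr.solve(X, Y)   # (2p) x 2
  est <- array(t(beta), dim = c(2, 2, p))
  expect_lt(max(abs(est - truth)), 0.03)
})

test_that("condition deltas remove the planted edge in the post network", {
  spec <- example_network_spec()
  gpost <- spectral_cgc(network_ss(spec, "post"))
  expect_true(all(gpost$values["HG", "TPa", ] <= 1e-8))
  gpre <- spectral_cgc(network_ss(spec, "pre"))
  b <- band_cgc(gpre)
  ## pre-condition influence concentrated in the gamma band
  expect_gt(b["HG", "TPa", "gamma"], 10 * b["HG", "TPa", "theta"])
})

test_that("trial simulation is reproducible and trial-independent", {
  spec <- example_network_spec()
  a <- simulate_network_trials(spec, "pre", 3, 50, seed = 9)
  b <- simulate_network_trials(spec, "pre", 3, 50, seed = 9)
  expect_identical(a$data, b$data)
  c_ <- simulate_network_trials(spec, "pre", 3, 50, seed = 10)
  expect_false(identical(a$data, c_$data))
})
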