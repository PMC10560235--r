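test_that("resampling preserves duration and tone amplitude", {
  n <- 8000
  tt <- (seq_len(n) - 1) / 2000
  rec <- recording(rbind(sin(2 * pi * 10 * tt), cos(2 * pi * 3 * tt)),
                   fs = 2000)
  ## 2000 -> 1000 Hz halves the sample count
  r2 <- resample_recording(rec, 1000)
  expect_equal(ncol(r2$samples), n %/% 2)
  ## identity when target equals current rate
  expect_identical(resample_recording(rec, 2000), rec)
  ## 10 Hz unit tone survives 2000 -> 100 Hz within 1%
  r3 <- resample_recording(rec, 100)
  mid <- 50:(ncol(r3$samples) - 50)
  amp <- sqrt(2 * mean(r3$samples[1, mid]^2))
  expect_lt(abs(amp - 1), 0.01)
  expect_error(resample_recording(rec, 4000), "upsampling")
})

test_that("Kaiser FIR band-pass meets its design", {
  fs <- 1000
  tt <- (seq_len(6000) - 1) / fs
  ## measure beyond the filter half-length from either edge
  mid <- 2000:4000
  ## 25 Hz unit sine passes the 0.5-50 Hz 3624-tap filter within 2%
  y <- fir_bandpass(sin(2 * pi * 25 * tt), fs = fs)
  expect_lt(abs(sqrt(2 * mean(y[mid]^2)) - 1), 0.02)
  ## DC is rejected
  y0 <- fir_bandpass(rep(5, 6000), fs = fs)
  expect_lt(max(abs(y0[mid])), 1e-3)
  ## 80 Hz is attenuated by at least 40 dB
  y80 <- fir_bandpass(sin(2 * pi * 80 * tt), fs = fs)
  expect_lt(sqrt(2 * mean(y80[mid]^2)), 10^(-40 / 20))
  expect_error(fir_bandpass(tt, fs = fs, low = 10, high = 600), "Nyquist|band")
})

test_that("first-PC removal strips rank-1 high-frequency common mode", {
  fs <- 1000
  n <- 4000
  withr::with_seed(5, {
    clean <- matrix(rnorm(4 * n), 4)
    clean <- fir_bandpass(clean, fs = fs, low = 1, high = 100, taps = 501)
    artifact <- sin(2 * pi * 340 * (seq_len(n) - 1) / fs) * 20
    gains <- c(1, 0.8, 1.2, 0.9)
    rec <- recording(clean + outer(gains, artifact), fs = fs)
  })
  out <- remove_first_pc(rec, hp_cutoff = 300)
  hp_power <- function(x) {
    h <- fir_bandpass(x, fs = fs, low = 320, high = 360, taps = 501)
    mean(h[500:3500]^2)
  }
  expect_lt(hp_power(out$samples[1, ]) / hp_power(rec$samples[1, ]), 0.01)
  expect_error(remove_first_pc(recording(matrix(1:10, 1), fs = 100)),
               "2 channels")
})

test_that("epoching uses the half-open window and drops edge events", {
  fs <- 1000
  rec <- recording(matrix(rep(5, 2 * 10000), 2), fs = fs)
  ev <- data.frame(onset_s = c(0.05, 2, 5, 9.9), duration_s = 0.5,
                   bias = c("b", "p", "b", "p"))
  expect_warning(
    ep <- epoch_and_baseline(rec, ev, window = c(-0.15, 0.8),
                             baseline = c(-0.15, 0)),
    "dropped 2 of 4")
  expect_equal(dim(ep$data), c(2L, 2L, 950L))
  expect_equal(ep$annotations$bias, c("p", "b"))
  ## constant signal with full-epoch baseline -> all zeros
  ep0 <- epoch_and_baseline(rec, data.frame(onset_s = 5, duration_s = 0.5),
                            window = c(-0.15, 0.8), baseline = c(-0.15, 0.8))
  expect_lt(max(abs(ep0$data)), 1e-12)
})

test_that("ensemble normalization yields mean 0 and SD 1 at every point", {
  ep <- noise_epochs(20, 3, 60, seed = 6)
  ep$data <- ep$data * 3 + 2
  out <- normalize_trials_for_cgc(ep)
  mu <- apply(out$data, c(2, 3), mean)
  sd_ <- apply(out$data, c(2, 3), sd)
  expect_lt(max(abs(mu)), 1e-10)
  expect_lt(max(abs(sd_ - 1)), 1e-10)
  ## identical trials -> zero ensemble SD error naming the point
  ident <- epochs(array(rep(1:60, each = 6), dim = c(2, 3, 60)), fs = 100)
  expect_error(normalize_trials_for_cgc(ident), "zero ensemble SD")
  ## evoked component common to all trials is removed
  withr::with_seed(7, {
    tmpl <- sin(2 * pi * 5 * (0:59) / 100)
    dat <- array(rnorm(40 * 1 * 60), dim = c(40, 1, 60))
    for (i in 1:40) dat[i, 1, ] <- dat[i, 1, ] + 4 * tmpl
    epe <- epochs(dat, fs = 100)
  })
  oute <- normalize_trials_for_cgc(epe)
  resid_cor <- abs(cor(colMeans(oute$data[, 1, ]), tmpl))
  expect_lt(resid_cor, 0.2)
})

test_that("speech-responsive channel selection applies the duration rule", {
  fs <- 1000
  make_ep <- function(deflect_ms, amp, seed) {
    withr::with_seed(seed, {
      dat <- array(rnorm(30 * 1 * 950), dim = c(30, 1, 950))
    })
    tt <- -0.15 + (0:949) / fs
    idx <- tt >= 0.1 & tt < 0.1 + deflect_ms / 1000
    dat[, 1, idx] <- dat[, 1, idx] + amp
    epochs(dat, fs = fs, t_start = -0.15, baseline = c(-0.15, 0))
  }
  ## 200 ms, strong deflection -> selected
  sel <- select_speech_responsive(make_ep(200, 5, 8))
  expect_equal(sel$selected, "ch1")
  ## an 80 ms deflection fails the 125 ms rule even with a little noise
  ## crossing the threshold elsewhere
  sel2 <- select_speech_responsive(make_ep(80, 5, 8))
  expect_equal(length(sel2$selected), 0L)
  ## pure-noise channels are rarely selected
  hits <- sum(vapply(1:20, function(s) {
    length(select_speech_responsive(make_ep(0, 0, 100 + s))$selected)
  }, numeric(1)))
  expect_lte(hits / 20, 0.05)
  expect_error(select_speech_responsive(make_ep(200, 5, 8),
                                        response_window = c(0, 0.1)),
               "min_duration")
})

test_that("ROI averaging pools member channels correctly", {
  ep <- noise_epochs(50, 3, 40, seed = 9)
  ep$labels <- c("a", "b", "c")
  ## single-channel ROI is the identity
  one <- average_roi(ep, c(a = "A"))
  expect_equal(one$data[, 1, ], ep$data[, 1, ])
  ## two independent-noise channels -> ROI variance about halved
  two <- average_roi(ep, c(b = "BC", c = "BC"))
  ratio <- var(as.vector(two$data)) / var(as.vector(ep$data[, 2, ]))
  expect_lt(abs(ratio - 0.5), 0.1)
  expect_error(average_roi(ep, c(zz = "Z")), "unknown channels|no member")
})
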