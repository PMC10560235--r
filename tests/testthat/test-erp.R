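make_labeled_epochs <- function(mismatch_amp, seed, n_channels = 1,
                                noise_sd = 2, fs = 250) {
  roster <- label_congruency(roster_intraop(seed = seed))
  spec <- evoked_effect_spec(
    peak1 = list(latency = 0.25, amplitude = -8, width = 0.03,
                 vot_slope_ms = 8),
    peak2 = list(latency = 0.35, amplitude = 6, width = 0.04,
                 vot_slope_ms = 8),
    mismatch = list(amplitude = mismatch_amp, window = c(0.27, 0.35)),
    noise_sd = noise_sd)
  simulate_evoked_trials(roster, spec, fs = fs, window = c(-0.15, 0.8),
                         n_channels = n_channels, seed = seed)
}

test_that("mismatch difference recovers the planted component", {
  ep <- make_labeled_epochs(mismatch_amp = 4, seed = 21)
  dw <- mismatch_difference(ep, filter = list(low = 0.5, high = 50,
                                              taps = 801, kaiser_beta = 5.65))
  expect_equal(dw$n_congruent, 96L)
  expect_equal(dw$n_incongruent, 96L)
  win <- dw$times >= 0.29 & dw$times <= 0.33
  ## congruent - incongruent: planted +4 on incongruent appears as about -4
  expect_lt(abs(mean(dw$values[1, win]) - (-4)), 1)
})

test_that("difference wave vanishes without a mismatch component", {
  ep <- make_labeled_epochs(mismatch_amp = 0, seed = 22)
  dw <- mismatch_difference(ep, filter = NULL)
  win <- dw$times >= 0.25 & dw$times <= 0.4
  ## |mean| below a few noise / sqrt(n) units
  expect_lt(abs(mean(dw$values[1, win])), 3 * 2 / sqrt(96))
})

test_that("condition swap negates the difference wave", {
  ep <- make_labeled_epochs(mismatch_amp = 4, seed = 23)
  dw <- mismatch_difference(ep, filter = NULL)
  swapped <- ep
  cg <- swapped$annotations$congruency
  swapped$annotations$congruency <- ifelse(cg == "congruent", "incongruent",
                                           ifelse(cg == "incongruent",
                                                  "congruent", cg))
  dw2 <- mismatch_difference(swapped, filter = NULL)
  expect_equal(dw2$values, -dw$values, tolerance = 1e-12)
})

test_that("unbalanced conditions are rejected with counts", {
  ep <- make_labeled_epochs(mismatch_amp = 4, seed = 24)
  drop1 <- which(ep$annotations$congruency == "congruent")[1]
  ep2 <- ep
  ep2$annotations <- ep$annotations[-drop1, ]
  ep2$data <- ep$data[-drop1, , , drop = FALSE]
  expect_error(mismatch_difference(ep2, filter = NULL),
               "95 congruent vs 96 incongruent")
})

test_that("VOT peak latencies shift by the planted slope", {
  ## near-noise-free trials so the template peaks are measured directly
  ep <- make_labeled_epochs(mismatch_amp = 0, seed = 25, noise_sd = 0.05,
                            fs = 1000)
  pm <- vot_peak_measures(ep)
  expect_equal(nrow(pm), 6L)
  fit1 <- coef(lm(lat1_s ~ vot_step, pm))[2] * 1000
  fit2 <- coef(lm(lat2_s ~ vot_step, pm))[2] * 1000
  expect_lt(abs(fit1 - 8), 1)
  expect_lt(abs(fit2 - 8), 1)
  expect_true(all(pm$amp1 < 0))
  expect_true(all(pm$amp2 > 0))
  ## latencies confined to their search windows
  expect_true(all(pm$lat1_s >= 0.175 & pm$lat1_s <= 0.325))
  expect_true(all(pm$lat2_s >= 0.275 & pm$lat2_s <= 0.425))
})

test_that("flat peak windows resolve to the earliest extremum with a flag", {
  dat <- array(0, dim = c(4, 1, 500))
  ep <- epochs(dat, fs = 500, t_start = -0.1,
               annotations = data.frame(vot_step = c(1, 1, 2, 2)))
  expect_warning(pm <- vot_peak_measures(ep), "flat")
  expect_true(all(pm$flat1))
  expect_equal(pm$lat1_s, rep(min(pm$lat1_s), 2))
})
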