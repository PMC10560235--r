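two_phase_roster <- function(seed = 1) {
  rbind_rosters <- function(a, b) {
    out <- rbind(as.data.frame(a), as.data.frame(b))
    out$trial_id <- seq_len(nrow(out))
    class(out) <- c("trial_roster", "data.frame")
    out
  }
  rbind_rosters(roster_extended(phase = "pre", seed = seed),
                roster_extended(phase = "post", seed = seed + 1))
}

test_that("behavior simulation respects limits and symmetry", {
  r <- roster_extended()
  ## all-zero parameters: /p/ rate about 0.5
  resp <- simulate_behavior(r, params = list(), seed = 2)
  expect_lt(abs(mean(resp$response) - 0.5), 3 * 0.5 / sqrt(nrow(resp)))
  ## a huge VOT slope gives a step function at the continuum midpoint
  step <- simulate_behavior(r, params = list(vot = 1e6), seed = 3)
  expect_true(all(step$response[step$vot_step >= 4] == 1))
  expect_true(all(step$response[step$vot_step <= 3] == 0))
  expect_identical(simulate_behavior(r, params = list(vot = 1), seed = 4),
                   simulate_behavior(r, params = list(vot = 1), seed = 4))
})

test_that("psychometric fit recovers generator coefficients", {
  truth <- list(intercept = 0.2, vot = 1.2, bias = 0.8, disconnection = -0.9,
                vot_disc = -0.6, bias_disc = 0.3, word_pair_sd = 0.25)
  resp <- simulate_behavior(two_phase_roster(10), params = truth, seed = 11)
  fit <- fit_psychometric(resp, n_boot = 300, seed = 12)
  co <- fit$coefficients
  tv <- c(truth$intercept, truth$vot, truth$bias, truth$disconnection,
          truth$vot_disc, truth$bias_disc)
  within2 <- abs(co$estimate - tv) <= 2 * co$se
  expect_gte(sum(within2), 5)
  ## coding conventions: VOT slope and bias must carry their planted signs
  expect_gt(co$estimate[co$term == "vot"], 0.8)
  expect_lt(co$estimate[co$term == "disconnection"], 0)
})

test_that("flat post-disconnection slope shows in the curves", {
  truth <- list(intercept = 0, vot = 1.5, bias = 0.5, disconnection = 0,
                vot_disc = -1.4, bias_disc = 0)
  resp <- simulate_behavior(two_phase_roster(20), params = truth, seed = 21)
  cv <- psychometric_curves(resp)
  slope_of <- function(ph) {
    d <- cv[cv$phase == ph & cv$bias == "p", ]
    coef(lm(p_resp ~ vot_step, d))[2]
  }
  expect_lt(slope_of("post") / slope_of("pre"), 1)
})

test_that("psychometric curves match a brute-force groupby", {
  resp <- simulate_behavior(roster_extended(), params = list(vot = 1),
                            seed = 30)
  cv <- psychometric_curves(resp)
  expect_true(all(cv$p_resp >= 0 & cv$p_resp <= 1, na.rm = TRUE))
  for (i in sample(nrow(cv), 5)) {
    sel <- resp$bias == cv$bias[i] & resp$vot_step == cv$vot_step[i] &
      resp$phase == cv$phase[i]
    expect_equal(cv$p_resp[i], mean(resp$response[sel]))
    expect_equal(cv$n[i], sum(sel))
  }
  ## deterministic step responder: 0 then 100%
  step <- simulate_behavior(roster_extended(), params = list(vot = 1e6),
                            seed = 31)
  cs <- psychometric_curves(step)
  expect_true(all(cs$p_resp[cs$vot_step <= 3] == 0))
  expect_true(all(cs$p_resp[cs$vot_step >= 4] == 1))
  ## empty cells are reported as missing, not zero
  sub <- resp[resp$vot_step != 3, ]
  cv2 <- psychometric_curves(sub)
  expect_true(all(is.na(cv2$p_resp[cv2$vot_step == 3])))
})

test_that("reliable change index follows the Jacobson-Truax form", {
  ## pre = post: RCI 0, not significant
  r0 <- reliable_change_index(10, 10, r = 0.8, sd = 3)
  expect_equal(r0$rci, 0)
  expect_false(r0$significant)
  ## worked case: r = 0.8, sd = 3, change 4 -> RCI = 2.108, significant
  r1 <- reliable_change_index(10, 14, r = 0.8, sd = 3)
  expect_equal(r1$rci, 4 / (3 * sqrt(2) * sqrt(0.2)), tolerance = 1e-12)
  expect_equal(round(r1$rci, 3), 2.108)
  expect_true(r1$significant)
  ## boundary identity at exactly 1.96
  delta <- 3 * sqrt(2) * sqrt(0.2) * 1.96
  expect_true(reliable_change_index(0, delta, 0.8, 3)$significant)
  ## antisymmetry
  expect_equal(reliable_change_index(14, 10, 0.8, 3)$rci, -r1$rci)
  expect_error(reliable_change_index(1, 2, r = 1, sd = 3), "reliability")
  expect_error(reliable_change_index(1, 2, r = 0.5, sd = 0), "sd")
})

test_that("separation falls back to a penalized fit with a warning", {
  r <- roster_extended()
  resp <- simulate_behavior(r, params = list(vot = 1e6), seed = 40)
  expect_warning(fit <- fit_psychometric(resp, n_boot = 50, seed = 41),
                 "separation")
  expect_true(all(is.finite(fit$coefficients$estimate)))
})
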