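#' Simulate binary psychometric responses from a roster
#'
#' Draws Bernoulli /p/ responses for the experimental trials of a roster
#' from a logistic model whose linear predictor mirrors the psychometric
#' analysis model: centered VOT step, sentence bias (+/- 0.5 for /p/ vs
#' /b/), disconnection phase (+/- 0.5 for post vs pre) and the two
#' interactions with disconnection, plus an optional Gaussian word-pair
#' random intercept.
#'
#' @param roster a [make_task_roster()] roster with `phase` and `vot_step`.
#' @param params named list of generator coefficients: `intercept`, `vot`,
#'   `bias`, `disconnection`, `vot_disc`, `bias_disc`, and `word_pair_sd`
#'   (>= 0, SD of per-word-pair intercepts).
#' @param seed integer seed.
#' @return The roster restricted to experimental rows, with columns
#'   `response` (1 = /p/), `vot_c`, `bias_c`, `disc_c` appended.
#' @export
simulate_behavior <- function(roster,
                              params = list(intercept = 0, vot = 1.5,
                                            bias = 1, disconnection = 0,
                                            vot_disc = 0, bias_disc = 0,
                                            word_pair_sd = 0),
                              seed = 1) {
  stopifnot(inherits(roster, "trial_roster"))
  if (!all(c("phase", "vot_step") %in% names(roster))) {
    stopf("roster must have phase and vot_step")
  }
  p <- utils::modifyList(list(intercept = 0, vot = 0, bias = 0,
                              disconnection = 0, vot_disc = 0,
                              bias_disc = 0, word_pair_sd = 0), params)
  if (p$word_pair_sd < 0) stopf("word_pair_sd must be >= 0")
  dat <- as.data.frame(roster[roster$trial_class == "experimental", ])
  steps <- sort(unique(dat$vot_step))
  dat$vot_c <- dat$vot_step - mean(steps)
  dat$bias_c <- ifelse(dat$bias == "p", 0.5, -0.5)
  dat$disc_c <- ifelse(dat$phase == "post", 0.5, -0.5)
  with_seed(seed, {
    wps <- unique(dat$word_pair)
    wp_eff <- stats::setNames(stats::rnorm(length(wps), sd = p$word_pair_sd),
                              wps)
    eta <- p$intercept + p$vot * dat$vot_c + p$bias * dat$bias_c +
      p$disconnection * dat$disc_c + p$vot_disc * dat$vot_c * dat$disc_c +
      p$bias_disc * dat$bias_c * dat$disc_c + wp_eff[dat$word_pair]
    dat$response <- stats::rbinom(nrow(dat), 1, stats::plogis(eta))
  })
  class(dat) <- c("trial_roster", "data.frame")
  dat
}
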