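#' Build a speech-prediction task roster
#'
#' Generates the trial table for the sentence-bias / voice-onset-time (VOT)
#' word categorization task. Experimental trials cross word pair x VOT step x
#' sentence bias, each cell repeated `reps` times; filler trials are fully
#' predictive sentences and catch trials present the target word visually.
#' The VOT continuum has `vot_steps` evenly spaced steps from 0 to 40 ms
#' (6 steps: 0, 8, 16, 24, 32, 40 ms).
#'
#' Two designs are of particular interest and available as presets:
#' the extended (perioperative) design with 7 word pairs, 6 VOT steps,
#' 2 biases, 6 repetitions, 126 filler and 63 catch trials (693 trials in
#' total, 504 of them experimental), and the intraoperative design with
#' 4 word pairs, 6 reps and 72 fillers (288 experimental trials, 24 per
#' bias x VOT cell).
#'
#' @param word_pairs number of /b/-/p/ minimal word pairs.
#' @param vot_steps number of VOT continuum steps (6 for the standard design).
#' @param biases number of sentence-bias conditions (2: /b/ and /p/ bias).
#' @param reps repetitions per word pair x VOT x bias cell.
#' @param filler number of filler trials.
#' @param catch number of catch trials.
#' @param phase recording phase label attached to every row
#'   (`"pre"` or `"post"`).
#' @param seed integer seed; the roster row order is shuffled
#'   deterministically given the seed. `NULL` keeps the systematic order.
#' @return A `data.frame` of class `trial_roster` with columns `trial_id`,
#'   `trial_class` (experimental/filler/catch), `word_pair`, `bias`
#'   (`"b"`/`"p"` or `NA`), `vot_step` (1-based), `vot_ms`, `congruency`
#'   (filled by [label_congruency()]), `phase`.
#' @seealso [label_congruency()], [roster_extended()], [roster_intraop()]
#' @examples
#' r <- make_task_roster(word_pairs = 7, vot_steps = 6, biases = 2,
#'                       reps = 6, filler = 126, catch = 63)
#' nrow(r)                      # 693
#' sum(r$trial_class == "experimental")  # 504
#' @export
make_task_roster <- function(word_pairs, vot_steps = 6L, biases = 2L,
                             reps = 1L, filler = 0L, catch = 0L,
                             phase = "pre", seed = NULL) {
  for (nm in c("word_pairs", "vot_steps", "biases", "reps", "filler",
               "catch")) {
    if (!is_count(get(nm))) stopf("%s must be a non-negative integer", nm)
  }
  if (word_pairs > 0 && biases > 0 && vot_steps > 0 && reps <= 0) {
    stopf("invalid design: reps must be positive when experimental cells exist")
  }
  vot_grid <- if (vot_steps > 1) seq(0, 40, length.out = vot_steps) else
    rep(0, vot_steps)
  bias_lvls <- c("b", "p")[seq_len(min(biases, 2L))]
  if (biases > 2L) stopf("at most 2 bias conditions are supported")

  exp_rows <- if (word_pairs > 0 && biases > 0 && vot_steps > 0 && reps > 0) {
    g <- expand.grid(rep = seq_len(reps),
                     vot_step = seq_len(vot_steps),
                     bias = bias_lvls,
                     word_pair = paste0("wp", seq_len(word_pairs)),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    data.frame(trial_class = "experimental",
               word_pair = g$word_pair,
               bias = g$bias,
               vot_step = g$vot_step,
               vot_ms = vot_grid[g$vot_step],
               stringsAsFactors = FALSE)
  } else NULL
  other <- function(n, cls) {
    if (n == 0) return(NULL)
    data.frame(trial_class = cls, word_pair = NA_character_,
               bias = NA_character_, vot_step = NA_integer_,
               vot_ms = NA_real_, stringsAsFactors = FALSE)[rep(1, n), ]
  }
  roster <- rbind(exp_rows, other(filler, "filler"), other(catch, "catch"))
  if (is.null(roster)) {
    roster <- data.frame(trial_class = character(), word_pair = character(),
                         bias = character(), vot_step = integer(),
                         vot_ms = numeric(), stringsAsFactors = FALSE)
  }
  if (!is.null(seed) && nrow(roster) > 0) {
    roster <- with_seed(seed, roster[sample.int(nrow(roster)), , drop = FALSE])
  }
  roster <- cbind(trial_id = seq_len(nrow(roster)), roster)
  roster$congruency <- rep(NA_character_, nrow(roster))
  roster$phase <- rep(phase, nrow(roster))
  rownames(roster) <- NULL
  class(roster) <- c("trial_roster", "data.frame")
  roster
}

#' @rdname make_task_roster
#' @export
roster_extended <- function(phase = "pre", seed = NULL) {
  make_task_roster(word_pairs = 7L, vot_steps = 6L, biases = 2L, reps = 6L,
                   filler = 126L, catch = 63L, phase = phase, seed = seed)
}

#' @rdname make_task_roster
#' @export
roster_intraop <- function(phase = "pre", seed = NULL) {
  make_task_roster(word_pairs = 4L, vot_steps = 6L, biases = 2L, reps = 6L,
                   filler = 72L, catch = 0L, phase = phase, seed = seed)
}

#' Label trial congruency for the mismatch (ERP) contrast
#'
#' Experimental trials are congruent when the target word endpoint matches
#' the sentence bias: /b/-biased sentences with the two shortest VOT steps
#' (0 and 8 ms) or /p/-biased sentences with the two longest steps (32 and
#' 40 ms). The reversed combinations are incongruent. Middle continuum steps
#' are ambiguous and labeled `"n/a"`; filler and catch trials stay `NA`.
#'
#' @param roster a `trial_roster` from [make_task_roster()].
#' @return The roster with its `congruency` column filled.
#' @examples
#' r <- label_congruency(roster_intraop())
#' table(r$congruency)   # 96 congruent, 96 incongruent
#' @export
label_congruency <- function(roster) {
  if (!inherits(roster, "trial_roster")) stopf("roster must be a trial_roster")
  ex <- roster$trial_class == "experimental"
  if (any(ex & (is.na(roster$bias) | is.na(roster$vot_step)))) {
    stopf("experimental rows must have bias and vot_step")
  }
  ns <- max(roster$vot_step[ex], 0L)
  short <- c(1L, 2L)
  long <- c(ns - 1L, ns)
  cong <- (roster$bias == "b" & roster$vot_step %in% short) |
          (roster$bias == "p" & roster$vot_step %in% long)
  incong <- (roster$bias == "b" & roster$vot_step %in% long) |
            (roster$bias == "p" & roster$vot_step %in% short)
  roster$congruency[ex] <- ifelse(cong[ex], "congruent",
                                  ifelse(incong[ex], "incongruent", "n/a"))
  roster
}

#' Read or write a trial roster / behavioral response table as TSV
#'
#' @param x a `trial_roster` (or response table) data frame.
#' @param path file path.
#' @return `read_roster` returns a `trial_roster`; `write_roster` returns
#'   `path` invisibly.
#' @export
write_roster <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_roster
#' @export
read_roster <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         na.strings = "", stringsAsFactors = FALSE)
  class(x) <- c("trial_roster", "data.frame")
  x
}

#' @export
print.trial_roster <- function(x, ...) {
  cat(sprintf("Trial roster: %d trials (%d experimental, %d filler, %d catch)\n",
              nrow(x), sum(x$trial_class == "experimental"),
              sum(x$trial_class == "filler"), sum(x$trial_class == "catch")))
  NextMethod()
}
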