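Package: sscgc
Title: State-Space Spectral Conditional Granger Causality for Pre/Post
    Lesion Network Analysis of Intracranial Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for directed network inference from multichannel,
    trial-based electrophysiological recordings, built around spectrally
    resolved conditional Granger causality computed from innovations-form
    state-space models identified by a covariance-driven subspace method.
    Includes phase-randomization surrogate thresholds and trial-permutation
    tests for pre- versus post-condition connectivity changes, weighted-degree
    hub testing with edge-permutation nulls, evoked-response analysis (ERSP
    with decibel baseline normalization, voice-onset-time peak latencies,
    congruency mismatch difference waves) with cluster-based permutation
    statistics, psychometric logistic modeling of speech categorization, and
    a synthetic-data module that generates trial rosters, coupled stochastic
    oscillator networks, evoked responses and behavioral responses with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
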