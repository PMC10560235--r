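---
title: "State-space spectral conditional Granger causality for pre/post disconnection analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{State-space spectral conditional Granger causality for pre/post disconnection analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sscgc)
```

This vignette documents the models, estimators and design decisions behind
`sscgc`. The package addresses a concrete analysis problem: given
multichannel trial-based electrophysiological recordings obtained before
and after a focal disconnection of part of a cortical network, quantify
directed (effective) connectivity between the recorded regions, decide
which directed influences changed, test hub-like centrality of nodes, and
characterize the accompanying changes in evoked responses and behavior.

## 1. Signal conditioning

The preprocessing chain mirrors standard intracranial practice: recordings
are decimated with a zero-phase Kaiser anti-alias FIR
(`resample_recording()`, e.g. 2000 to 1000 Hz for evoked analyses and to
100 Hz for connectivity), cleaned of rank-1 broadband artifacts by removing
the first principal component of the high-pass (> 300 Hz) covariance
(`remove_first_pc()`), optionally notch-filtered at the line frequency, and
epoched around stimulus onsets with per-trial baseline subtraction
(`epoch_and_baseline()`, default window −150 to 800 ms, baseline −150 to
0 ms, half-open sample windows, trials too close to the recording edge are
dropped and logged, never padded). Channels enter the connectivity analysis
only if they are speech-responsive: the trial-averaged response must exceed
`k_sd = 2` baseline standard deviations for a cumulative 125 ms within the
500 ms target-word window (`select_speech_responsive()`). The baseline SD
is computed across time on the trial-averaged baseline; this choice (rather
than across trials, or both) is exposed as an argument. Channels are then
averaged into ROIs (`average_roi()`).

Before model fitting, `normalize_trials_for_cgc()` removes the ensemble
mean and scales by the ensemble SD at every (channel, time) point. This
removes the trial-locked evoked component, so the state-space model is
fitted to the induced, stochastic dynamics; conditional GC is invariant to
the per-channel rescaling this implies.

Line-noise denoising is implemented as zero-phase FIR notch filters at the
line frequency and harmonics (`notch_line()`); a demodulation-based
transform would serve the same role but its internals belong to a different
toolchain, and notch filtering is the functional equivalent here.

## 2. The state-space model and its identification

The innovations form

$$x_{t+1} = A x_t + K \epsilon_t, \qquad y_t = C x_t + \epsilon_t$$

is identified by covariance-driven canonical variate analysis (CVA).
Lagged covariances $\Lambda_l = E[y_{t+l} y_t']$ are estimated within each
trial (no cross-trial wraparound; $1/T$ normalization so pooled sequences
stay positive semidefinite) and pooled across trials. With past/future
horizon $k$ (default $\max(20, 2m)$ block rows), the block-Hankel
covariance between future and past is whitened by the Cholesky factors of
the past and future block-Toeplitz covariances; the singular values of the
whitened Hankel matrix are the canonical correlations between past and
future, i.e. the cosines of the principal angles between the two subspaces.
The leading $m$ canonical directions define the state filter
$x_{t+1} = J\,p_t$ (state covariance = the canonical correlations), and
$A$, $C$, $K$, $\Sigma$ follow from covariance regressions of
$x_{t+2}, y_{t+1}$ on $x_{t+1}$, all expressible in the pooled lag
covariances. Estimates outside the admissible region are projected back
(spectral radius of $A$ capped below 1; $K$ shrunk if the innovations
filter is not invertible); both events are rare at the problem sizes used
here.

Working from pooled per-trial covariances has a practical consequence the
package exploits heavily: a surrogate or permutation iteration that only
reassigns trials to groups re-identifies the model from re-pooled
covariances in milliseconds, which is what makes thousands of full
re-identifications per test affordable.

**Order selection.** `select_order()` counts the canonical correlations
(equivalently, principal angles below $\pi/2$) that exceed a null
threshold built by shuffling the pairing between past and future blocks
across trials and time, which destroys temporal dependence while keeping
the marginal structure; the threshold is the $1-\alpha$ quantile
($\alpha = 0.05$) of the surrogate maximum canonical correlation. White
noise yields order 0; an order of 15, as used for real multi-ROI
recordings, is an ordinary configuration.

## 3. Spectral conditional Granger causality

From the model, $H(f) = C(e^{2\pi i f/f_s} I - A)^{-1} K + I$ and
$S(f) = H \Sigma H^*$. For source $j$ and target $i$, the reduced model
observing all channels but $j$ shares the state equation; its gain $K^R$
and innovations covariance $\Sigma^R$ solve the stochastic-realization
discrete algebraic Riccati equation (DARE) for the sub-observation, using
the model-implied covariances ($\bar G = A\Pi C' + K\Sigma$,
$\Lambda_0 = C\Pi C' + \Sigma$ with $\Pi$ the state covariance). The DARE
is solved by fixed-point iteration of the covariance form (tolerance
$10^{-10}$, at most $10^4$ iterations, ridge regularization on
positive-definiteness failures). With $B(f)$ the reduced model's inverse
transfer function, the map $B(f) H_r(f)$ carries full-model innovations to
reduced-model innovations, and Geweke's conditional spectral GC is

$$f_{j \to i \mid \text{rest}}(f) = \ln S^*_{ii}(f) - \ln\left(
  S^*_{ii}(f) - |(B H_r)_{ij}(f)|^2\, \Sigma_{jj|\text{rest}} \right),$$

where $S^*_{ii}$ is computed from the factored form (guaranteeing
nonnegative values up to rounding; values in $(-10^{-8}, 0)$ are clipped to
zero, anything more negative raises an error). The time-domain counterpart
$\ln(\Sigma^R_{ii}/\Sigma_{ii})$ is returned alongside. For unconditional
pairs (two-channel models) the frequency average of the spectral GC equals
the time-domain GC essentially exactly — the reduced innovations spectrum
is flat, and the Kolmogorov–Szegő log-integral closes the second term. For
*conditional* GC the identity is only approximate: the partialled term's
log-integral equals the innovations variance of a residual process that is
not white, so deviations of several percent (occasionally tens of percent
on pairs with near-zero GC) are expected and are not an implementation
defect; the test suite records this behavior on randomized systems. The default frequency grid is 0–50 Hz in 0.5 Hz steps at the
100 Hz connectivity sampling rate; band aggregates are unweighted means
over in-band bins for theta (4–8 Hz), alpha (9–12), beta (13–30) and gamma
(31–50).

Two properties give independent leverage on correctness, and both are
exercised in the tests: (i) on randomized stable VAR systems the entire
spectrum matches a brute-force oracle built from full/reduced VAR
regressions on analytic autocovariances (multivariate Levinson–Whittle
recursion) with coefficient-polynomial spectra, to well under 2% relative
L2; (ii) GC is invariant under arbitrary invertible changes of the state
basis.

## 4. Surrogate and permutation inference on connectivity

`phase_randomize()` replaces Fourier phases per trial and channel with
i.i.d. uniform phases (conjugate-symmetric, DC/Nyquist real), exactly
preserving each channel's amplitude spectrum while destroying
cross-channel dependence in expectation. `surrogate_threshold()` re-runs
identification + spectral CGC on each surrogate ensemble (same model
order; order re-selection under phase randomization is unstable and adds
nothing), takes the cell-wise $1-\alpha$ empirical quantile (defaults
$\alpha = 0.05$, 2000 surrogates for full runs), subtracts it from the
observed spectrum and trims at zero.

`permutation_prepost()` tests condition differences: the statistic per
ordered pair and band is the sum over in-band frequencies of the absolute
difference between the pre- and post-condition GC spectra; the null
reassigns trials to conditions at random and re-runs both identifications
(2000 permutations for full runs; 500 in the scaled test profile);
p-values are exceedance counts divided by the permutation count (no +1
correction, selectable), FDR is controlled at $q = 0.05$ across pairs ×
bands, and the reported direction is the sign of the post-minus-pre band
mean. Surrogate thresholds are computed separately per condition when both
are thresholded.

## 5. Hub testing

Hub strength of a node is its weighted degree — the sum of incoming and
outgoing edge weights in a band-aggregated GC matrix — and the hub
statistic contrasts a target node against the median of the comparison
nodes (the median being robust to extreme surrogate draws). The null
permutes the off-diagonal edge weights over off-diagonal positions,
preserving the weight multiset exactly; the one-sided p-value is the
surrogate exceedance fraction (100000 surrogates for full runs). A
pairwise-swap chain is the documented alternative realization; full
permutation is equivalent to running such a chain to mixing. Across the
four bands, p-values are BH-corrected at 0.05.

## 6. Evoked responses

`compute_ersp()` uses analytic Morlet wavelets (default 7 cycles,
frequency-domain implementation) and expresses trial-averaged power in dB
relative to the mean baseline power per frequency (default baseline −150
to 0 ms). The default converts the trial-mean power to dB; the per-trial
dB convention is available via `db_per_trial`. Near epoch edges (within a
few wavelet SDs) zero-padding attenuates power estimates, so baselines
should keep a margin from the left epoch edge; tests quantify the flatness
of the noise ERSP away from edges. Band summaries use inclusive-bounds
bin means; the ERSP band set adds low gamma 31–70 and high gamma
70–150 Hz.

`mismatch_difference()` computes congruent-minus-incongruent difference
waves from FIR-filtered condition ERPs (0.5–50 Hz, 3624 taps, Kaiser
$\beta = 5.65$, zero-phase application by exact group-delay compensation),
after matching the conditions by VOT rank (shortest with shortest) so
VOT-driven latency shifts cancel. `vot_peak_measures()` measures the
negative peak around 250 ms and positive peak around 350 ms (default
search windows ±75 ms, earliest extremum on ties, flagged) per VOT step;
pre/post latency comparisons use `wilcoxon_signed_rank()` (exact for
n ≤ 25 without ties, otherwise normal approximation with continuity and
tie corrections).

`cluster_permutation_test()` forms clusters from pointwise two-sided Welch
t statistics at `cluster_alpha = 0.05` (the pointwise statistic is a
package choice), scores them by summed |t|, builds the max-cluster-mass
null over label permutations, and discards significant clusters shorter
than 25 ms. The duration rule is applied after p evaluation.

## 7. Behavior

`simulate_behavior()` draws /p/ responses from a logistic model with
centered VOT step, ±0.5-coded sentence bias and disconnection phase, both
interactions with disconnection, and Gaussian word-pair intercepts.
`fit_psychometric()` fits the fixed-effects logistic model and obtains
standard errors by a cluster bootstrap over word pairs (default 2000
resamples, with the standard $G/(G-1)$ few-cluster variance correction),
approximating the random-factor structure of a mixed model without
re-implementing mixed-model machinery; exact mixed fits are out of scope.
With only 7 word-pair clusters, ±2 SE intervals have t-like (df ≈ 6)
rather than normal coverage — roughly 90% rather than 95% — which is an
inherent property of few-cluster inference, not of the estimator choice
(a leave-one-cluster-out jackknife gives the same coverage). Quasi-complete
separation falls back to a small-ridge IRLS fit with a warning.
`reliable_change_index()` implements the Jacobson–Truax form
$\mathrm{RCI} = (\text{post} - \text{pre}) / (sd\sqrt{2}\sqrt{1-r})$ with
externally supplied norm SD and test-retest reliability, flagged at
±1.96.

## 8. The synthetic-data generator

`network_spec()` defines damped stochastic oscillators — AR(2) nodes with
poles at radius `damping` and angle $2\pi f_0/f_s$ — coupled by short
causal cosine-burst FIR kernels (one carrier cycle, 2–6 taps,
L2-normalized to the coupling gain) placed at a given lag, so each
directed influence is concentrated around its band's center frequency.
Per-condition coupling overrides emulate pre/post edge removal. The
implied VAR is checked for companion-form stability, and
`network_var()`/`network_ss()` expose the exact generator, so theoretical
GC spectra are available for any spec. Trials are independent stationary
realizations (400-sample burn-in), 0–2 s at 100 Hz by default.

`example_network_spec()` fixes the pre/post study conditions used by the
tests: five nodes labeled after the recorded regions, a beta and a theta
coupling from the frontal node, and a gamma-band coupling HG → TP-analog
(gain 0.12) removed post. Two deliberate choices deserve comment. First,
kernels are kept short: longer (narrower-band) kernels raise the
generator's VAR order beyond what moderate analysis model orders represent,
and the resulting order-truncation misfit shifts GC estimates across the
whole network between conditions. Second, the removed edge is weak and its
endpoints carry no other couplings: with strong coupling, the endpoints'
shared variance induces finite-sample reverse-direction GC and
conditioning-set effects that genuinely differ between conditions — the
trial-permutation test then correctly flags them, but they are estimator
artifacts rather than ground-truth edges. At gain 0.12 the removed edge is
still detected with essentially full power at 100 trials/condition while
the rest of the network stays quiet. Additive observation noise was
considered and rejected for the generator: sensor noise on a coupled
target genuinely creates reverse-direction influence (the source's clean
copy in the coupled node predicts the noisy target), changing the ground
truth itself.

The evoked generator (`simulate_evoked_trials()`) plants two
VOT-latency-shifted Gaussian peaks (negative near 250 ms, positive near
350 ms, default slope 8 ms per VOT step), a Gaussian mismatch component on
incongruent trials, optional per-phase band-limited power effects and
white trial noise. It emulates the trial-average structure of auditory
evoked responses, not their single-trial waveform statistics, spatial
covariance or 1/f background — so passing tests validate the measurement
code, not physiological realism.

Task rosters (`make_task_roster()`) cross word pair × VOT step × bias with
a fixed repetition count; the extended design (7 pairs, 6 reps, 126
fillers, 63 catch) totals 693 trials with 504 experimental, and the
intraoperative design (4 pairs, 6 reps) gives 288 experimental trials, 24
per bias × VOT cell, yielding 96 congruent and 96 incongruent trials for
the mismatch contrast. The VOT grid is 0–40 ms in 6 even steps (interior
values assumed even; endpoints and step count are given). The per-cell
repetition counts are inferences from the printed totals and are exposed
as arguments.

## 9. Problem sizes, numerics, limitations

The test and acceptance profiles scale the published analysis settings
down to desk size as the package's own test design: 500 surrogates /
permutations instead of 2000, 10⁴ edge swaps instead of 10⁵, 100
trials/condition, 2 s trials at 100 Hz, model order 14 and horizon 20 for
the five-ROI network. Full-scale settings remain the documented defaults
of the user-facing functions.

Numerical choices: resolvents are evaluated by eigendecomposition with a
1-norm condition guard and per-frequency solves as fallback; covariance
Cholesky factors get a relative jitter ladder on failure; identified
innovations covariances are ridged to positive definiteness when a
regression-residual estimate is marginal; empirical quantiles use the
$\lceil (1-\alpha) n \rceil$ order statistic.

Known limitations: the generator and estimator are linear and stationary —
no cross-frequency coupling, no time-varying connectivity; conditional GC
at finite trial counts carries small positive bias on dependent pairs,
which the surrogate thresholding absorbs but raw band aggregates retain;
ERSP low frequencies are unreliable within a wavelet width of epoch
edges; cluster tests are 1-D (time), not time-frequency; and the
psychometric model omits lapse/guess parameters, so strongly flattened
post-surgical curves are summarized by slope changes only.
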