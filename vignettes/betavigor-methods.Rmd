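---
title: "Methods: beta coherence and power as trial-level predictors of movement vigor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: beta coherence and power as trial-level predictors of movement vigor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

Movement vigor — how quickly a movement is initiated and executed — is
classically indexed behaviorally by reaction time (RT) and movement time
(MT), and neurally by the movement-related suppression of beta-band
(13–30 Hz) power over contralateral motor cortex. Local beta power,
however, discriminates instructed Fast from Slow movements with
inconsistent *direction* across people: about half show lower, half
higher beta power in Fast trials. A network-level alternative is
imaginary coherence (iCoh) between the contralateral motor cortex (left
precentral seed) and fronto-parietal cortical parcels: the magnitude of
the imaginary part of the normalized cross-spectrum, which is blind to
instantaneous (zero-lag) signal mixing and therefore robust to volume
conduction. `betavigor` implements the complete comparison of those two
candidate predictors as a reusable, tested pipeline, together with a
synthetic cohort generator that plants the statistical structure the
analysis is designed to detect — so every stage can be validated against
known ground truth without any external recording.

## The synthetic cohort generator

`sim_config()` / `simulate_cohort()` generate, per subject and trial,
parcel-level time courses, mixed sensor epochs, and kinematic traces.

* **Coupling (the coherence effect).** Each trial's seed parcel carries a
  band-limited Gaussian carrier (unit variance, zero-phase FIR-filtered
  white noise in the configured band). Each *coupled* parcel receives
  `kappa * shift(seed) + (1 - kappa) * noise`, where `shift` is a
  quarter-cycle phase shift (`coupling_phase = pi/2`, the lag that
  maximizes imaginary coherence) and `kappa` depends on the trial's
  condition: `kappa_slow = 0.8` vs `kappa_fast = 0.2` by default, i.e. a
  planted contrast of 0.6 centred on 0.5. The symmetric centring makes
  the coupled parcel's *variance* condition-invariant, so the coherence
  manipulation does not leak into parcel power. Band-limited noise
  carriers (not sinusoids) keep the coherence estimator nontrivial:
  windows contain only a handful of independent samples, so estimates
  carry realistic small-sample bias.
* **Per-subject heterogeneity.** The coupling contrast varies across
  subjects (`kappa_sd = 0.15` on the kappa scale, truncated to the valid
  range); a zero planted contrast propagates exactly, giving a null
  cohort. A subject's *coherence effect* is recorded on the directional
  Fast-minus-Slow scale (negative when Slow coupling is stronger), which
  is also the scale of the decoder's coefficients under the package's
  sign convention.
* **Power effects.** Each subject receives a Fast-vs-Slow seed power
  offset in dB, drawn from `N(0, 1.5 dB)` — random sign by construction,
  reproducing the roughly 50/50 split of power-effect directions as a
  cohort property. The offset scales the seed parcel's local trace only,
  not the coupling component, and iCoh is scale-invariant, so power and
  coherence manipulations stay orthogonal.
* **Sensor mixing.** Channels are a fixed, full-rank Gaussian
  leadfield-like mixture of the parcels plus 1/f noise (exponent 1.0).
  Each parcel is anchored near one channel (the seed at the
  C3-equivalent channel "D19"); the four coupled parcels are anchored at
  mutually distant channels. The latter is deliberate: coupled parcels
  share a carrier, so their *covariance* is condition-dependent, and a
  channel pooling two of them would convert that covariance into a
  spurious sensor-power contrast, contaminating the planted
  power-vs-coherence dissociation.
* **Behavior.** Per-trial RT and MT are drawn around per-condition means
  (Fast 350/250 ms, Slow 500/600 ms, trial-level SDs 50–120 ms — typical
  values for instructed-speed hand-opening tasks), snapped to the 100 Hz
  behavioral sampling grid. Luminosity traces carry five bumps (hand
  fully open: one RT anchor plus four movement repetitions); the
  accelerometer trace has burst amplitude proportional to 1/MT, so mean
  |acceleration| is genuinely higher in Fast trials. A Gaussian copula
  couples the subject's coherence effect to their Slow−Fast RT+MT
  difference at `rho_behavior = -0.6` on the coefficient scale
  (between-subject SD 0.15 s).

**What the generator does not emulate:** within-epoch temporal dynamics
(no event-related desynchronization time course — effects are constant
across the epoch), pre-neurofeedback baseline epochs, eye or muscle
artifacts, and realistic head-model forward fields. Passing tests
therefore demonstrate that the *analysis machinery* recovers planted
trial-level structure, not that it handles every artifact class of real
recordings. One emergent interaction worth knowing: symmetric
orthogonalization redistributes the shared coupling component, which
slightly *suppresses* the uncoupled parcels' chance-level iCoh in Slow
trials; the sign-proportion statistic over all 21 fronto-parietal
parcels is therefore not cleanly directional on strongly coupled
cohorts, even though the coupled-parcel effect itself is large.

## Spectral and connectivity estimation

* **Windows.** Seven 0.5 s analysis windows centred on the go cue with
  50% overlap, from −1.0 to +1.0 s; baseline windows are the three
  printed pre-neurofeedback windows. The published baseline list skips
  [−1.25, −0.75]; it is kept exactly as printed.
* **Sensor power.** Morlet wavelets (7 cycles, 1 Hz steps across the
  band), per-frequency squared magnitude, averaged across frequencies,
  then within windows. Averaging the *complex* coefficients across
  frequencies before squaring cancels phase and is available only behind
  `average_complex_first = TRUE` for comparison. Baseline dB correction
  is `10*log10(power/baseline)` with a time-invariant baseline.
* **Source path.** Zero-phase FIR band-pass (Hamming windowed-sinc,
  2 Hz transition; two-pass application via the squared-magnitude
  frequency response, mathematically identical to forward–backward
  filtering with zero-padded edges), decimation to 128 Hz (the band-pass
  itself anti-aliases for integer factors; polyphase resampling
  otherwise), per-trial symmetric orthogonalization on the filtered real
  signals, Hilbert analytic signal, and trimming of the 0.2 s edge
  margins to [−1.5, +1.5] s.
* **Symmetric orthogonalization** finds the closest set of mutually
  orthogonal time courses (closest-orthonormal matrix with per-parcel
  magnitudes refit, iterated to `1e-10`, max 50 iterations), applied per
  trial on demeaned signals. It is order-independent and, on random
  full-rank problems, changes the data less than sequential
  Gram–Schmidt. Exact zero-lag-mixing invariance of iCoh holds only in
  the infinite-sample limit; at the window lengths used here the
  residual sensitivity is at the estimator's noise floor (order 0.01–
  0.05), which the tests document.
* **iCoh** is estimated per trial and window as the magnitude of the
  imaginary part of the sample-normalized cross-spectrum. No across-trial
  averaging: the pipeline stores trial-resolved tensors, accepting the
  documented small-sample bias (about `sqrt(1/(pi*K))` for K independent
  samples under independence). Zero-power windows yield NA, never a
  silent 0.

## Screening, group statistics

Before across-trial averaging, trials are screened per condition,
channel/parcel, and window by `|x - median| > 3 * MAD` with the *raw*
MAD (no 1.4826 normality constant — the rule is stated directly in MAD
units; note that 3 raw MADs is about 2 standard deviations for normal
data, so flagging is deliberately aggressive). Masking is cell-wise — a
trial can be excluded for one channel–window cell and retained
elsewhere — with a whole-trial variant behind a flag. Masking never
alters retained values, and the mask is a pure function of raw storage.

The paired cluster-based permutation test thresholds per-unit paired
t-values at the two-sided alpha quantile, clusters supra-threshold units
by spatial adjacency (edges between units closer than 0.02 montage
units) and sign, scores clusters by summed t, and builds the null from
within-subject condition swaps (sign flips) with the +1 permutation
correction. The sign-proportion test flips each subject's whole
difference map; its statistic (proportion of parcels with Fast < Slow)
saturates when effects are strong and homogeneous across parcels — in
that regime the null flips reproduce the saturated statistic whenever
fewer than half the subjects flip, so the test has power only with
subject-level noise of comparable size. This is a property of the
statistic, documented here because the tests construct fixtures
accordingly.

## Decoding

Each candidate *group* is one channel or parcel with all 7 windows (21
features max per model at 3 groups). Sequential forward selection adds
the best remaining group while the gain in leakage-safe 5-fold
stratified CV AUC is at least 0.002 (first step: the best single group
must beat chance by the same margin), stopping at 3 groups. Within each
training fold, trials are cleaned per condition by the 3×MAD rule (a
trial is dropped when any feature in the current model flags it;
features with zero MAD — degenerate cells, e.g. duplicated bootstrap
trials — carry no trial-level outlier information and are skipped), then
features are z-scored with training-fold statistics applied unchanged to
the test fold. The classifier is L1 logistic regression at fixed inverse
regularization C = 1 (glmnet lambda `1/(C*n)`); no inner tuning loop.
The fit descends a short warm-started lambda path ending at the target
value — single-lambda coordinate descent is fragile on near-separable
resamples (it can exhaust its iteration budget and return an empty
model), while the path converges reliably with coefficient differences
in the third decimal. Folds are drawn once per subject and reused
across all SFS evaluations so candidates compete on identical splits.

Outcome coding: **Fast = 1**, so a negative standardized coefficient
means the feature is *lower in Fast* trials; `coding = "slow1"` flips
it. This resolves the ambiguity between the printed outcome coding and
the printed interpretation of negative coefficients in favour of the
interpretation, and the convention is asserted end-to-end by test.

Bootstrap stability: 1000 stratified resamples of the trials with
replacement (class counts preserved), each rerunning the full 5-fold CV
on the frozen selection; the 95% CI is percentile-based. Subjects whose
CI overlaps 0.5 are excluded from the consistency aggregation.

**Selection bias, measured and reported.** The reported per-subject AUC
is the selected model's cross-validated AUC — the quantity the original
analysis reports. Because SFS picks the best of ~21 noisy AUC estimates
(each with standard error near 0.05), this quantity is optimistically
biased under the null: label-permuted cohorts yield mean AUCs near
0.65–0.70, not 0.5, and no reading of the procedure (fresh-fold
re-evaluation, bootstrap aggregation) removes the bias, since the
selected features' spurious association is a property of the dataset
itself. The package does not hide this: `cv_auc()` alone is
chance-calibrated (verified by test), the acceptance suite measures the
full-pipeline null bias explicitly, and `scripts/acceptance.R` reports
it as `null_delta_auc`. Planted-effect recovery claims are therefore
made against this measured null, not against 0.5.

## Inference

Group tests consume per-subject summaries only: one-sample t of mean
AUCs against 0.5; two-sided one-sample t of mean coefficients against 0
(above-chance subjects only; skipped with a warning below 5 subjects);
one-sided Pearson correlations (negative direction expected) between
mean coefficients and the Slow−Fast difference in RT+MT, MT, or RT;
partial correlation by double least-squares residualization with
df = n − 3; and the artifact control correlating trial-wise |acc| with
the trial-mean beta feature. With planted condition effects in both
behavior and signals, the artifact-control correlation is *expected* to
be strong in synthetic cohorts — it tests the plumbing, and its null
calibration is tested on independent draws.

The four-way dissociation (coherence consistency negative and power
consistency null; coherence–vigor correlation negative and power–vigor
null) is verified in two regimes. The decoding route uses the default
cohort (strong contrast), where the consistency contrast is sharp but
decoder coefficients saturate: with near-perfect class separation the
L1 coefficient magnitude is set by the regularizer, not the effect size,
so between-subject coefficient *variation* no longer tracks the planted
contrast and the decoded coefficient–vigor correlation is uninformative
there. The correlation half of the pattern is therefore tested on the
planted-effect scale at n = 30 (where the copula's −0.6 has full power)
and, for the decoder, in the moderate-contrast regime that matches the
published operating point (delta-AUC ≈ 0.15–0.3), where coefficient
magnitude does track the contrast (measured correlation ≈ −0.7).

## Problem sizes and numerical choices

Test-suite problem sizes are chosen to exercise every stage at
meaningful power: the planted-recovery and dissociation blocks run the
full pipeline on the default cohort (12 subjects × 120 trials) with 200
bootstrap resamples (the package default stays 1000, used by
`scripts/acceptance.R` and the analysis scripts); decoding calibration
uses 50 label-permuted subjects; cluster-test calibration uses 100 null
cohorts at 500 permutations; determinism is checked on a 6-subject
cohort, since bit-level reproducibility is size-independent. Trial
counts below roughly 30 per condition are not recommended for decoding:
the per-fold MAD cleaning of 21-feature models can then exhaust a class,
which surfaces as the documented fold-redraw/error path rather than a
silent degradation.

Other numerical choices: FFT lengths are padded to 5-smooth sizes;
wavelet support is ±4 sigma; AUC is the Mann–Whitney rank statistic
(ties give 0.5; cross-checked against pROC); permutation p-values carry
the +1 correction; SFS ties break by candidate order; master seeds fan
out deterministically to every stochastic stage, so a fixed seed gives
byte-identical reports.

## Known limitations

* The generator's effects are stationary within the epoch; analyses that
  depend on within-epoch dynamics (e.g. pre- vs post-cue contrasts)
  see only noise differences between windows.
* The sign-proportion and cluster tests are implemented for the 2-D
  synthetic montage; real high-density montages only require supplying
  their positions/adjacency.
* The selection-bias property discussed above is inherent to the
  published selection-then-report design; users comparing against
  chance should use the measured null (`null_delta_auc`) or a permuted
  cohort, not 0.5.
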