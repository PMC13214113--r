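# betavigor

Beta-band cortico-cortical coherence versus local beta power as
trial-level predictors of movement vigor.

## The problem

Instructed movement speed (Fast vs Slow) modulates reaction time (RT)
and movement time (MT); their sum is an inverse proxy for movement
vigor. The classical neural index of vigor is the movement-related
suppression of beta-band (13–30 Hz) power over contralateral motor
cortex, but its *direction* is notoriously inconsistent across people. A
network-level alternative is seed-based imaginary coherence (iCoh): for
the left precentral (motor) seed and another cortical parcel with
analytic signals x and y,

    iCoh = | Im( Sxy / sqrt(Sxx * Syy) ) |,   Sxy = <x * conj(y)>,

the magnitude of the imaginary part of the normalized cross-spectrum —
insensitive to zero-lag volume conduction. `betavigor` implements, as a
tested R pipeline, the full comparison of the two predictors:

* a **synthetic cohort generator** that plants (i) seed–parcel beta
  coupling stronger in Slow than Fast trials, (ii) per-subject
  Fast−Slow power offsets of random sign, and (iii) faster behavior in
  Fast trials, with a configurable across-subject correlation between
  the coherence effect and the Slow−Fast RT+MT difference;
* **kinematics**: RT/MT/amplitude/|acc| extraction from luxmeter and
  accelerometer traces, 3×MAD outlier marking, paired tests with a
  Shapiro normality gate (Cohen's dz / matched-pairs rank-biserial r);
* **spectral features**: Morlet band power in seven 0.5 s windows
  around the go cue, baseline dB correction; zero-phase FIR filtering,
  decimation to 128 Hz and Hilbert analytic signals for the source path;
* **connectivity**: per-trial symmetric (closest-orthogonal, order-
  independent) orthogonalization and the seed-based iCoh tensor;
* **group statistics**: cell-wise 3×MAD trial screening, paired
  cluster-based spatial permutation tests, top-parcel ranking, and the
  sign-proportion permutation test;
* **decoding**: grouped sequential forward selection (one parcel or
  channel × 7 windows per group, gain ≥ 0.002, ≤ 3 groups) around L1
  logistic regression in leakage-safe stratified 5-fold CV, with
  bootstrap AUC confidence intervals; negative coefficients mean the
  feature is lower in Fast trials;
* **inference**: group tests of AUCs against chance, coefficient
  consistency across subjects, and one-sided correlations of decoder
  coefficients with the Slow−Fast RT+MT difference (plain and partial).

## Worked example

```r
library(betavigor)

cfg <- sim_config(n_subjects = 6, n_trials_per_condition = 30, rng_seed = 5)
cohort <- simulate_cohort(cfg)
rep <- run_end_to_end(cohort, run_config(n_boot = 50, n_perm = 200, seed = 11))

rep$decoding[["source-icoh"]]$table[1:3, c("subject", "mean_auc", "mean_coefficient", "selected")]
#>   subject  mean_auc mean_coefficient                                           selected
#> 1  sub-01 0.9888889       -0.1385255 postcentral-lh+caudalmiddlefrontal-lh+precuneus-lh
#> 2  sub-02 0.9111111       -0.6444461                                superiorparietal-rh
#> 3  sub-03 0.9222222       -0.2070113           precuneus-lh+postcentral-lh+precuneus-rh

unlist(rep$inference[["source-icoh"]]$consistency[c("t", "p")])
#>          t          p
#> -3.8222753  0.0123445
unlist(rep$inference[["sensor-power"]]$consistency[c("t", "p")])
#>          t          p
#> -0.3796981  0.7234681
```

Every subject decodes Fast vs Slow above chance from seed iCoh, the
selected parcels are dominated by the ones carrying the planted
coupling, and the mean coefficients are consistently negative (iCoh
lower in Fast, t = −3.8, p = 0.012), while the same test on power-based
models is null (t = −0.4, p = 0.72) — the planted dissociation.
`rep$behavior$tests` holds the MT/RT/amplitude/|acc| comparisons (here
MT: paired t = −10.0, p = 2e−4).

The `analysis/` directory holds the same workflow as numbered scripts
(`01_simulate.R` … `06_inference.R`), each writing its tables under
`results/`.

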