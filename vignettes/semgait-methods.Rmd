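---
title: "Methods: gait-cycle SEMG features and random-forest nerve-root localization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gait-cycle SEMG features and random-forest nerve-root localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semgait)
```

## The clinical problem and the measurement model

Most lumbar disc herniations compress either the L5 or the S1 nerve root,
and the two roots innervate different ankle muscles: L5 chiefly the
tibialis anterior (TA, dorsiflexor, normally active around heel strike),
S1 chiefly the gastrocnemius (LG, plantarflexor, normally peaking in late
stance). Compression therefore leaves muscle-specific fingerprints in
surface EMG recorded during walking:

* **L5 compression** — the symptomatic-side TA activation peak is delayed
  from early in the gait cycle (~5–11 %) into mid-stance (~35 %), producing
  co-contraction with LG; TA spectral content (MPF/MF) drops.
* **S1 compression** — the symptomatic-side LG peak moves forward from late
  stance (~44 %) to mid-stance (~27 %), often leaving a second, smaller
  late-stance burst (a bimodal envelope); LG MPF/MF drop and its peak
  amplitude falls.
* **Healthy** walking is left–right symmetric.

Four parameters per muscle and side summarize a recording: the **RMS peak**
(µV) of the gait-cycle-averaged windowed-RMS envelope, its **peak time**
(% of the gait cycle), and the **mean (MPF)** and **median (MF) power
frequency** (Hz) of the per-cycle spectrum. The classifier input is the
*absolute bilateral difference* of each parameter (symptomatic −
asymptomatic for patients, left − right for controls), eight features in
the fixed order `diff_feature_names()`. A 50-tree random forest maps these
to the three classes (healthy / L5 / S1).

## Feature extraction

Per channel, `extract_subject()` applies:

1. **Band-pass 20–500 Hz** (`bandpass()`): 4th-order Butterworth run
   forward–backward (zero phase). Peak *timing* is an endpoint of the
   analysis, so phase distortion is not acceptable; zero-phase filtering is
   the standard remedy.
2. **Segmentation** (`segment_cycles()`): cycle *k* spans the half-open
   interval [heel-strike *k*, heel-strike *k*+1); sample membership uses
   0-based indices at time *i*/fs. The **first six complete cycles** are
   analysed; fewer than six is an error naming the channel, never a silent
   drop. "First six artifact-free" is a fixed, order-preserving rule — no
   data-dependent cherry-picking.
3. **Windowed RMS** (`rms_envelope()`): 30 ms windows stepped by 20 ms,
   starting at the cycle start; the last fully contained window is the
   final one; each value is stamped at the window center. On a 1.0 s cycle
   at 2000 Hz this yields 49 windows.
4. **Time normalization** (`normalize_envelope()`): window centers are
   mapped to percent of cycle and linearly interpolated onto the fixed
   0–100 % grid (101 points); positions outside the sampled range hold the
   nearest computed value.
5. **Envelope averaging** (`mean_envelope()`): the six normalized envelopes
   are averaged pointwise, **then** `peak_features()` takes the peak — the
   peak of the average, not the average of per-cycle peaks. Ties resolve to
   the first (earliest) grid position.
6. **Spectral features** (`spectral_features()`): one-sided periodogram of
   the whole cycle with a Hann taper (no sub-windowing — cycles are ~1 s,
   so bin spacing ~1 Hz is adequate and sub-windowing would trade
   resolution for variance reduction the averaging over six cycles already
   provides), restricted to 20–500 Hz. MPF = Σf·P/ΣP; MF interpolates the
   cumulative power linearly between bins. MPF/MF are computed per cycle
   and arithmetically averaged over the six cycles.

Scaling a channel by *c* > 0 scales the RMS peak by exactly *c* and leaves
peak time, MPF and MF unchanged; all outputs are invariant to sign flips.
Both invariances are tested.

## The synthetic-data generator

No public recordings exist for this problem, so the generator is a
first-class module, and its defaults *are* the study conditions. It has two
tiers.

**Raw-signal tier.** Each channel is synthesized as envelope × carrier:

* The **carrier** (`shaped_noise()`) realizes the classic two-corner
  parametric EMG spectrum
  P(f) = f_h⁴·f² / ((f² + f_l²)(f² + f_h²)²)
  by frequency-domain shaping: deterministic amplitudes √P(f_k), i.i.d.
  uniform phases, inverse FFT, exact unit RMS, exactly zero mean. Because
  the realized periodogram equals the target PSD up to discretization, the
  extracted MPF/MF can be checked against direct numerical integration of
  P(f) — every spectral feature has an analytic oracle.
* The **envelope** is a sum of Gaussian bursts positioned in percent of the
  cycle (`burst_spec()`). With a unit-RMS carrier, the windowed-RMS peak of
  a rendered burst equals the burst amplitude in expectation, so RMS peak
  and peak time also have built-in ground truth.
* `simulate_subject()` draws jittered cycle durations (mean 1.1 s, SD
  0.05 s — typical self-paced adult walking; the source cohorts report no
  gait timings), rounds them to the sample grid, places 9 heel strikes per
  side (8 complete cycles, so the six-cycle rule always has slack), offsets
  the contralateral side by half a cycle, and renders the four channels at
  2000 Hz.

Class-conditional defaults (`default_subject_profile()`) are calibrated so
that extracted features reproduce the published per-side cohort medians:
burst centers/amplitudes sit at the reported peak-time/RMS-peak medians,
and spectrum corners were fitted with `fit_spectrum()` so band-limited
MPF/MF match the reported values. Symptomatic-side spectral slowing is
implemented by lowering both corners. Two limitations are inherent to the
one-family carrier: over the 20–500 Hz band its MF/MPF ratio spans roughly
0.78–0.86, so cells whose reported MF exceeds the reported MPF (e.g. the
healthy TA pair) cannot be matched jointly — MPF is prioritized, and the
jointly infeasible pairs are all in cells where the source cohorts found no
strong side difference. Healthy raw profiles are calibrated to the
published single-side medians; their implied bilateral-difference medians
are smaller than the published difference table's, which is why
classifier-grade cohorts come from the feature tier.

**Feature tier.** `sample_feature_cohort()` draws the eight difference
features directly. Each class × feature cell of the published summary table
(median and quartiles; `diff_feature_reference()`) is converted to a
log-normal law by `lognormal_from_median_iqr()`: location = ln(median),
scale = (ln q3 − ln q1)/(2·z₀.₇₅) with z₀.₇₅ = 0.67449. The law has exactly
the requested median and approximately the requested IQR. Features are
sampled independently within class because only per-feature marginals are
published — real features are surely correlated, so passing performance
bounds on this cohort demonstrates that the *marginal* class structure
suffices, not that the generator reproduces the joint distribution. One
healthy quartile is printed as 0 (integer-rounded); it is stored as 0.5 —
half the printed resolution — so the log-scale fit is defined.

All generation is a pure function of (profile/distribution, seed). One
master seed is split into per-subject and per-repeat sub-streams by a
counter-based mix, so cohorts are reproducible regardless of generation
order, and every seeded function restores the caller's RNG state.

## Cohort statistics

* **Power analysis** (`required_sample_size()`, `achieved_power()`): exact
  two-sample two-tailed t-test power from the noncentral t distribution
  (df = 2n−2, noncentrality d·√(n/2)); the sample-size search increments n
  from 2, as dedicated power software does. For the study's planning values
  (d = 1.06, α = 0.05, power 0.95) the search yields 25 per group
  (power(24) = 0.949, power(25) = 0.957); the computation is verified
  against a Monte-Carlo oracle and the canonical d = 0.5/power = 0.80 → 64
  benchmark.
* **Normality screen** (`normality_flag()`): Kolmogorov–Smirnov with the
  Lilliefors correction, since location and scale are estimated from the
  data; constant samples are non-normal by convention. The decision is per
  variable per group.
* **Paired comparisons** (`paired_compare()`): paired t when both sides
  pass the screen, otherwise the Wilcoxon signed-rank test — the valid rank
  test for *related* samples. All-zero differences report p = 1.
* **Three-group comparisons** (`three_group_compare()`): one-way ANOVA if
  all groups pass the screen, else Kruskal–Wallis; pairwise tests have
  p-values multiplied by 3 (Bonferroni) and capped at 1. A `method`
  argument can force either branch, which the oracle-equality tests use.

## The diagnostic model and its validation

`train_model()` fits a random forest with 50 trees (the only published
hyperparameter); all other settings follow the field's defaults (√p
candidate features per split, unlimited depth, bootstrap resampling per
tree). Iterative error-threshold stopping criteria are not meaningful for
bagged ensembles — each tree is grown independently — so run length is
governed by tree count and repeat count alone.

`repeated_holdout()` performs 10 independent **stratified** 50/50 splits
(unstratified splits could starve a 29-subject class), trains a fresh
forest per repeat, and evaluates on the held-out half: accuracy,
macro-averaged precision/recall/F1 (macro treats the three roots
symmetrically; micro values are emitted alongside), Cohen's kappa
((p₀ − pₑ)/(1 − pₑ) with chance agreement from marginal products), and
one-vs-rest ROC AUC computed from class probabilities via the rank
(Mann–Whitney U) formulation, macro-averaged. The pooled 3×3 confusion
matrix is reported in counts and row percent, and impurity (Gini)
importances are averaged over repeats and normalized to shares.
`final_model()` retrains on the full cohort and reports importance shares;
on calibrated cohorts the TA RMS-peak-time difference ranks first.

Note one property of impurity importances established by the package's own
duplicate-column experiment: duplicating an informative column splits its
credit between the copies but *inflates* their summed share (duplicated
signal wins more splits), so importance shares are comparable within a
fixed feature set only.

## Problem sizes, tolerances and degenerate inputs

The test suite uses sizes chosen to make each check statistically sound:
10-second traces for spectral fidelity (5 % tolerance against the PSD
integral), 50 seeded simulations per class for parameter recovery
(extracted medians must fall inside the published dispersion bands —
quartiles for skewed cells, mean ± 3 SE for normal cells, the latter
because a published mean ± SE cell is compared against an extracted
*median*), 10⁵ draws per class for the feature-tier marginals (the widest
cell has log-scale SD ≈ 1.4, so the empirical median then carries ~0.5 %
standard error against a 3 % bound), 20 permutation runs for the
chance-level null, and a 10⁵-replicate Monte-Carlo oracle for power.
Degenerate inputs fail loudly: all-zero signals (undefined spectrum),
fewer than six cycles, cycles shorter than one window, single-class
training sets, and classes with one row all raise errors naming the
offending unit.

## Known limitations

* The raw-signal tier models stationary carriers inside Gaussian bursts;
  real EMG has motion artifacts, electrode noise, amplitude
  non-stationarity within bursts, and stride-to-stride envelope variability
  beyond duration jitter. Passing recovery tests shows the extraction chain
  is correct, not that it is robust to artifacts it never sees.
* Feature-tier cohorts have independent marginals; correlated features
  would likely make the classification problem easier or harder in ways the
  published summaries cannot constrain.
* MRI findings, kinematics beyond heel strikes, force-platform data and
  clinical scores (VAS/JOA) are out of scope; clinical scores pass through
  as metadata only.
* Onset-detection timing and MVC-normalized amplitudes are deliberately not
  implemented: the analysed timing feature is the envelope peak time, and
  amplitudes are absolute microvolts.
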