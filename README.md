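# semgait

Localization of compressed lumbar nerve roots (L5 vs S1) from bilateral
surface electromyography (SEMG) of the lower leg recorded during walking.

Lumbar disc herniation usually compresses a single nerve root — L5 or S1 —
and the two roots innervate different ankle muscles: L5 chiefly the
tibialis anterior (TA), S1 chiefly the lateral gastrocnemius (LG). Imaging
is static, so it cannot see how compression disturbs the muscles *in
motion*. During gait, however, the disturbance is characteristic: L5
compression delays the symptomatic TA activation peak from early in the
gait cycle (~5–11 %) into mid-stance (~35 %); S1 compression advances the
symptomatic LG peak from late stance (~44 %) to mid-stance (~27 %), often
bimodally; both lower the affected muscle's spectral content. `semgait`
turns these fingerprints into a diagnostic pipeline for clinicians and
gait-lab researchers:

* **Feature extraction** — per muscle and side, from raw EMG plus
  heel-strike events: band-pass 20–500 Hz (zero-phase Butterworth),
  segmentation into six gait cycles, 30 ms / 20 ms windowed RMS envelope
  normalized to the 0–100 % cycle grid, then four parameters: RMS peak
  (µV), RMS peak time (% of cycle), mean power frequency
  (MPF = Σf·P(f)/ΣP(f), Hz) and median frequency (MF, the half-power
  frequency), the spectral pair per cycle and averaged.
* **Bilateral-difference features** — the classifier input is
  |symptomatic − asymptomatic| (patients) or |left − right| (controls) for
  each of the 8 muscle × parameter combinations.
* **Cohort statistics** — noncentral-t power analysis, Lilliefors
  normality screening, paired signed-rank / t comparisons, Kruskal–Wallis
  or ANOVA with Bonferroni-adjusted pairwise tests.
* **Diagnosis** — a 50-tree random forest over the 8 features with three
  classes (healthy / L5 / S1), validated by 10 repeated stratified 50/50
  hold-out splits: accuracy, macro precision/recall/F1, Cohen's kappa,
  one-vs-rest macro ROC AUC, pooled confusion matrix, Gini importance
  shares.
* **Synthetic data** — a seeded generator at two tiers (raw four-channel
  recordings with class-conditional activation patterns, and
  classifier-ready feature tables drawn from log-normal laws fitted to
  published class medians/IQRs), so the whole chain is testable without
  any data download.

See `vignettes/semgait-methods.Rmd` for the models, calibration and design
choices.

## Worked example

Simulate one L5 patient, extract features, and inspect the fingerprint:

```r
library(semgait)
rec <- simulate_subject(default_subject_profile("L5", "left"), seed = 1)
extract_subject(rec)$features
#>   muscle  side rms_peak rms_peak_time      mpf       mf
#> 1     TA  left 46.45475            34 63.62283 50.93206
#> 2     TA right 33.95463            11 84.06050 69.96615
#> 3     LG  left 22.18795            42 83.94185 66.38762
#> 4     LG right 29.43666            43 89.49358 67.95977
```

The symptomatic (left) TA peaks at 34 % of the gait cycle versus 11 % on
the asymptomatic side — the delayed-dorsiflexor signature of L5
compression — and its MPF/MF are ~20 Hz lower.

Run the full cohort experiment (88 subjects: 30 healthy, 29 L5, 29 S1;
10 stratified 50/50 hold-out repeats of the 50-tree forest):

```r
cfg <- run_config(file.path(tempdir(), "demo"), seed = 1)
s <- run_pipeline(cfg)
#> [semgait] simulate (0.02 s) 88 feature rows -> .../demo/sim/cohort.csv
#> [semgait] stats (0.05 s) 5/8 features significant
#> [semgait] train (0.15 s) mean accuracy 0.889, kappa 0.833
#> [semgait] report (0.00 s) -> .../demo/run_summary.json
```

At this seed the validated model reaches mean accuracy 0.889, Cohen's
kappa 0.833 and macro one-vs-rest AUC 0.973; the most important feature is
`TA_RMSpeaktime_diff` (30 % importance share) — the TA timing asymmetry —
and the significant group-difference features are the RMS-peak and
RMS-peak-time differences of both muscles plus the LG MPF difference.
`run_summary.json` and per-stage CSV/JSON artifacts land under the output
directory. A thin command-line wrapper with the same stages lives at
`inst/cli/semgait.R`.

Power planning for a two-group follow-up at effect size d = 1.06
(two-tailed α = 0.05, power 0.95):

```r
required_sample_size(1.06, alpha = 0.05, power = 0.95)
#> [1] 25
```

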