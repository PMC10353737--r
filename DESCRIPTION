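Package: semgait
Title: Gait-Cycle Surface EMG Features and Random-Forest Localization of
    Compressed Lumbar Nerve Roots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for localizing compressed lumbar nerve roots (L5 vs S1)
    from bilateral surface electromyography (SEMG) of tibialis anterior and
    lateral gastrocnemius recorded during walking.  Provides gait-cycle
    synchronized feature extraction (windowed RMS envelope, RMS peak and peak
    time, mean and median power frequency), construction of absolute
    bilateral-difference features, cohort statistics (noncentral-t power
    analysis, normality screening, paired and three-group nonparametric
    comparisons with Bonferroni correction), a three-class random-forest
    diagnostic model with repeated stratified hold-out validation, and a
    seeded synthetic-data generator that emulates class-conditional walking
    EMG at both the raw-signal and feature-table level.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    randomForest,
    nortest,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
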