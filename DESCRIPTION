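Package: zsens
Title: Comparing the Relative Sensitivity of Disparate Repeated-Measures
    Outcome Measures via z-Score Standardization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Places heterogeneous behavioral, cognitive and physiological
    outcome measures from fully within-subject studies on a common scale by
    pooled z-score standardization, verifies that standardization leaves
    per-measure inference unchanged, and compares the measures' relative
    sensitivity to the study manipulation. Provides fully within-subject
    one-way and two-way (time x measure) repeated-measures ANOVA with
    Greenhouse-Geisser sphericity correction, orthogonal polynomial trend
    contrasts, Fisher's LSD pairwise comparisons, per-measure significance
    counts and standardized change magnitudes, a deterministic sensitivity
    ranking, and a synthetic-data generator that emulates a multi-metric
    stress study design for calibration and power checks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    optparse,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
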