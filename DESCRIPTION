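Package: dysbiome
Title: Longitudinal Multi-Omic Gut Microbiome Dysbiosis Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for longitudinal analysis of gut microbiome cohorts:
    a Bray-Curtis dysbiosis score with reference-percentile classification,
    censored exponential estimation of dysbiotic episode durations and
    intervals, kernel-density detection of microbiome shifts between
    consecutive samples, power-law models of within-subject temporal
    divergence, restricted-permutation PERMANOVA and Mantel tests for
    repeated measures, lenient cross-measurement-type temporal matching,
    per-feature random-intercept mixed models with residualization, and
    cross-measurement-type Spearman association networks. Includes a
    synthetic longitudinal multi-omic cohort generator with a two-state
    semi-Markov dysbiosis process so every stage is testable with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vegan,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
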