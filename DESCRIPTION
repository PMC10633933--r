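Package: hbqc
Title: Quality Control for Hemoglobin Distributions in Population Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes hemoglobin (Hb) distributions from field surveys of
    children 6-59 months and non-pregnant women of reproductive age and flags
    surveys whose distributions suggest measurement-quality problems. Computes
    per-survey summary statistics (mean, median, SD, bias-corrected skewness G1
    and excess kurtosis G2, WHO anemia prevalence), tabulates implausible-value
    flags across exclusion cutoffs, summarizes statistics across a survey
    corpus with subgroup-exclusion sensitivity and paired child/women
    comparisons, derives percentile-based plausibility thresholds for the SD of
    Hb, and evaluates each survey against a quality-control rule set (skewness
    above +0.2, excess kurtosis below -0.5, SD outside 1.1-1.55 g/dL for
    children or 1.1-1.65 g/dL for women, more than 1% of values outside
    4.0-18.0 g/dL). Includes a seeded Fleishman-polynomial generator of
    synthetic survey corpora with controllable moments, mean-SD coupling and
    gross-error contamination.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    jsonlite,
    yaml,
    MASS,
    rlang
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
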