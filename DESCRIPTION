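Package: nicomsm
Title: Weighted Multistate Markov Models for Youth Nicotine Product Transitions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Continuous-time multistate Markov modelling of transitions between
    four nicotine-product-use states (never use, non-current use, e-cigarette
    only, and cigarette smoking including dual use) from interval-censored
    longitudinal survey panels. Provides survey-weighted maximum-likelihood
    estimation of transition intensities with proportional-intensity covariate
    effects and piecewise-constant time-varying covariates, hazard-ratio
    tables, multi-year transition-probability projections with parametric
    bootstrap intervals, questionnaire-to-state coding rules for the two
    e-cigarette response formats used in UK household panel surveys, a
    synthetic panel generator with a known ground-truth model for parameter
    recovery studies, and an end-to-end pipeline including sensitivity
    analyses (wave exclusion, calendar-window exclusion, assumed-non-current
    exclusion, and a time-homogeneity check).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
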