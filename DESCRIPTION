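Package: multistagefit
Title: Multistage Models of Age-Specific Cancer Incidence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits multistage (Armitage-Doll type) models to age-specific
    cancer incidence rates on the log-log scale: the classical linear
    power-law model plus convex-upwards and concave-upwards generalizations
    that capture population heterogeneity or age-related acceleration and
    deceleration of carcinogenesis. Provides a hybrid fitting procedure
    (anchored linear regression plus an algebraic curvature solve with
    iterative refinement), R-squared based model selection, translation of
    fitted coefficients into mechanistic quantities (number of rate-limiting
    events, per-sequence probabilities, subgroup parameters), gender-combined
    slope algebra, a stochastic simulator of ordered rate-limiting event
    sequences with hazard estimation, a synthetic incidence-series generator,
    and CSV input/output with a small command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
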