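Package: neighborfactor
Title: Latent Neighborhood Factors from Tract-Level Demographics and Their
    Association with Poor Mental Health
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reduces a wide census-tract demographic table to a small set of
    oblique latent factors and quantifies each factor's association with a
    tract-level poor-mental-health prevalence. Implements catalog-driven
    feature selection (redundancy removal, coefficient-of-variation filtering,
    strata combination), skewness-minimizing Gaussianizing transformations,
    weighted k-nearest-neighbor imputation, exploratory factor analysis by the
    minimum-residual method with direct oblimin rotation, regression factor
    scores, bootstrap loading standard errors with congruence-based factor
    alignment, per-state cubic smoothing-spline fits summarized by R-squared,
    and a linear mixed-model variance decomposition yielding unique variance
    and Cohen's f-squared per factor. A synthetic-data generator with known
    latent structure makes the whole pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
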