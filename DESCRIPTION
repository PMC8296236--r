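Package: heatattr
Title: Heat-Attributable Mortality via Cross-Validated Temperature Metrics
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Two-stage distributed lag nonlinear modelling (DLNM) of daily
    warm-season temperature-mortality series across cities. Fits city-level
    quasi-Poisson time-series models with a natural-cubic-spline cross-basis
    over lagged temperature, pools lag-cumulated exposure-response curves by
    multivariate random-effects meta-analysis with best linear unbiased
    prediction (BLUP), locates the minimum mortality temperature (MMT) and
    percentile (MMP), selects the best of eight daily temperature metrics by
    leave-one-year-out cross-validation, and estimates heat-, extreme-heat-
    and moderate-heat-attributable fractions of mortality (HAF, EHAF, MHAF).
    Includes a synthetic multi-city panel generator with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    splines,
    MASS,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
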