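Package: ptarmiganRSF
Title: Resource Selection Functions for Willow Ptarmigan from Line-Transect Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to estimate exponential resource selection functions (RSF)
    for willow ptarmigan from line-transect distance-sampling surveys.
    Simulates synthetic landscapes and surveys with known selection
    coefficients, applies buffer and distance-deviation quality control with a
    full accounting ledger, generates detection-adjusted available locations by
    half-normal rejection thinning, fits mixed-effects used-available logistic
    regression with per-area random intercepts, selects models by AIC with a
    parsimony rule, and validates predictions by quantile-bin rank-correlation
    cross-validation and habitat-suitability mapping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
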