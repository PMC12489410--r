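Package: sharedplate
Title: Nutrient Intakes from Shared-Plate Food Records and Two-Method
    Validity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes individual daily nutrient intakes from structured
    image-voice food records collected in shared-plate eating settings:
    dual-analyst portion reconciliation, median-portion imputation, home
    recipe nutrient profiles with ingredient-level cooking retention
    factors, leftover handling, and even apportioning of shared servings
    across eaters. Compares two dietary assessment methods across three
    recording periods with a linear mixed model using nested random
    intercepts and iterative residual-variance-function weighting, and
    reports pairwise differences of weighted marginal means with
    confidence intervals alongside Bland-Altman agreement screens. A
    synthetic study generator with embedded ground truth makes the whole
    pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    lme4,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
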