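Package: forestatt
Title: Matching-Based Impact Evaluation of Protected Areas on Forest Loss
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A quasi-experimental pipeline for estimating the effect of
    protected areas, interacted with land-tenure regimes, on pixel-level
    forest loss. Provides bias-corrected nearest-neighbour matching with
    replacement (Mahalanobis and propensity-augmented metrics, propensity
    trimming and common support), normalized-difference balance diagnostics
    with balance-driven estimator selection, spillover (leakage) contrasts,
    partially linear models with wild-t bootstrap bands for treatment-effect
    heterogeneity along a biomass gradient, and avoided-deforestation and
    carbon extrapolation. Includes a synthetic-landscape generator with
    spatially autocorrelated covariates, a property tessellation carrying
    tenure labels, endogenous protection placement, and stored counterfactual
    outcomes that give ground-truth treatment effects for estimator
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    jsonlite,
    yaml,
    readr
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    broom,
    withr
Config/testthat/edition: 3
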