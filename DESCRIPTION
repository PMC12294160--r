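Package: famet
Title: Two-Stage Factor-Analytic Analysis of Multi-Environment Trials
    with Drought Envirotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-stage weighted analysis of plant-breeding
    multi-environment trials (MET). Stage one fits row-column mixed
    models to individual trials by REML, selects the spatial model by
    generalized heritability and produces un-shrunken genotype BLUEs
    with standard errors. Stage two fits factor-analytic FA(k) genetic
    variance structures to the weighted BLUEs, selects the factor order
    by AIC and derives rotated loadings, genetic correlations between
    environments and Factor Analytic Selection Tools (FAST): Shukla
    stability, performance-stability ranking and latent-regression
    diagnostics. An envirotyping layer computes vapor pressure deficit
    (VPD) and the self-calibrating Palmer Drought Severity Index
    (scPDSI) from station weather records, classifies environments by
    drought status, and links latent factors to environmental covariates
    and genotype scores to drought-tolerance indices (geometric mean
    productivity, relative decrease in yield). Includes generators for
    synthetic trial and weather data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    geosphere,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
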