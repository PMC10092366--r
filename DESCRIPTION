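Package: fastslowpop
Title: Population Trends, Environmental Change and the Fast-Slow
    Life-History Continuum
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for analysing vertebrate population
    trends against temperature and land-cover change, conditioned on
    species life-history strategies. Computes annual and mean log10
    rates of population change from abundance time series (with zero
    replacement, linear/GAM gap imputation and quality filtering),
    extracts per-population warming slopes and land-cover change rates,
    builds a fast-slow life-history axis from mass- and
    kinship-adjusted traits (with phylogenetic random-forest
    imputation), and fits linear mixed-effects models with backward
    AICc selection, type-III Wald tests, and Nakagawa pseudo-R2.
    Includes a synthetic-data generator with known ground truth and
    percentile-trimming / R2-threshold sensitivity analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    lme4,
    mgcv,
    purrr,
    randomForest,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    car,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
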