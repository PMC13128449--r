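Package: regrow
Title: Resistance, Return Rates and Recovery Times of Biodiversity Along
    Forest Chronosequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the resilience of ecological communities recovering
    from agricultural land use along a space-for-time chronosequence.
    Computes per-plot abundance, alpha Hill diversity (orders 0, 1, 2) and
    compositional similarity to an old-growth reference (Bray-Curtis,
    Hill-number overlap transforms, Jaccard), fits a negative-exponential
    recovery trajectory per land-use legacy, and decomposes resilience into
    resistance, return rate, recovery time and relative recovery after a
    fixed horizon, with leave-one-plot-out jackknife confidence intervals.
    Includes cross-taxon comparative statistics (random-forest predictor
    importance, rank correlations, paired and grouped nonparametric tests
    with false-discovery-rate control), a presence/absence mode for
    literature-derived datasets, and a seeded synthetic chronosequence
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
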