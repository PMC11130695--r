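Package: baskettrend
Title: Trend Analysis of Grocery Purchase Prices and Nutrient Density
    Across Ordinal Income-Adequacy Groups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable, tested pipeline for analysing loyalty-card grocery
    purchase data against an ordinal measure of perceived income adequacy
    (PIA). Aggregates transaction-level purchases into per-participant,
    per-food-group expenditure, volume, energy, prices (euro/kg and euro/MJ),
    energy and expenditure shares, and a Nutrient Rich Food Index (NRFI);
    tests for monotone trends across PIA levels with a two-sided
    Jonckheere-Terpstra test, with and without inverse-probability weighting
    for confounding by education and sex, under Benjamini-Hochberg false
    discovery rate control; and ships a synthetic-data generator with known,
    configurable PIA gradients and confounding so every stage of the pipeline
    is verifiable without proprietary retailer data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    withr,
    nnet,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
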