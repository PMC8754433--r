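Package: pvsignal
Title: Pharmacovigilance Signal Detection with Empirical Bayes Shrinkage and
    Graphical-Lasso Drug Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for disproportionality analysis of spontaneous adverse
    drug event (ADE) reports. Ingests case-level reports, normalizes drug
    names to active ingredients, and builds drug-by-ADE contingency tables
    with independence-baseline expected counts. Scores drug-ADE pairs with
    the relative reporting ratio and the Gamma-Poisson Shrinker empirical
    Bayes model (EBGM, EB05/EB95 posterior quantiles), applies staged signal
    filters (report-count floor, pulmonary term subsetting, RR and EB05
    selection rules), clusters drugs by graphical-lasso sparse precision
    estimation of their EBGM profiles with retention-calibrated penalty
    tuning and reverse Cuthill-McKee ordering, and tests class homogeneity
    with Friedman and Wilcoxon signed-rank statistics. Includes a synthetic
    spontaneous-report generator with known ground truth for end-to-end
    validation.
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
    igraph,
    jsonlite,
    Matrix,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
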