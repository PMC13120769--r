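Package: ecoguilds
Title: Inferring Resource Competition and Metabolic Guilds from Microbial
    Abundance Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates environment-mediated consumer-resource communities with
    guild-structured resource preferences under sinusoidal or
    Ornstein-Uhlenbeck resource supply, and infers resource competition from
    abundance time series using four pairwise coupling measures: equal-time
    correlation, its absolute value, total cross-power-spectral-density
    magnitude, and total magnitude-squared coherence (Welch-averaged).
    Provides link and guild detection by thresholding and single-linkage
    clustering with ROC/AUC evaluation against the ground-truth
    resource-utilization overlap, and an empirical mode that relates the
    pairwise measures of relative-abundance tables to Jukes-Cantor sequence
    distance with an index-shuffle null model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    dplyr,
    generics,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    ggplot2,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr,
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
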