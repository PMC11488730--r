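Package: agemicro
Title: Multi-Cohort Meta-Analysis of the Aging Gut Microbiome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for multi-kingdom, multi-cohort gut
    microbiome meta-analysis across age groups: quantile-matching batch
    correction with a PERMANOVA R-squared evaluation grid, alpha/beta
    diversity with an inter-study homogeneity filter, per-feature linear
    model differential abundance with BH-FDR, per-age-group Pearson
    co-occurrence networks with walktrap community detection,
    hypergeometric enrichment of differentially abundant taxa in network
    clusters, age-stage signature calling, and interaction-shift analysis.
    Includes a seeded logistic-normal multinomial simulator that plants
    batch effects, group effects, correlated taxon blocks, signatures and
    network rewiring, with machine-readable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    igraph,
    vegan,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
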