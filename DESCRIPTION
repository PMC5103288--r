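Package: mycopop
Title: Population Genomics of Fungal Strain Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for population-genomic analysis of resequenced
    dikaryotic fungal strain collections such as cultivated and wild shiitake
    (Lentinula edodes). Provides variant filtering and distance thinning,
    windowed nucleotide diversity and Tajima's D, per-strain heterozygosity
    and inbreeding coefficients, hierarchical analysis of molecular variance
    (AMOVA), neighbour-joining phylogeny, Weir-Cockerham F_ST at sites and in
    5-kb windows, a Bayesian F_ST-outlier scan based on the
    multinomial-Dirichlet model with reversible-jump MCMC, divergence-window
    set logic for candidate gene assignment, group-specific missense SNP
    enrichment via Fisher's exact test, and min-max phenotype normalisation
    with complete-linkage clustering. A Balding-Nichols multi-population
    genotype simulator with ground-truth tables supports parameter-recovery
    testing throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
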