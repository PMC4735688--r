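Package: raretree
Title: Demographic Inference and Ancestry Mapping from Rare-Allele Site Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits population-tree demographic models (split times and per-branch
    effective sizes) to the joint distribution of rare derived alleles across
    populations, using a coalescent likelihood that tracks derived-lineage
    configurations exactly while approximating non-derived lineages by their
    expectation. Includes maximum-likelihood and MCMC parameter inference,
    placement of single (optionally ancient) genomes onto a fitted tree by
    scanning merge points with age-aware freezing, a rare-allele-sharing
    ancestry-fraction pipeline, a structured-coalescent Monte-Carlo simulator
    that serves as a brute-force oracle, and tools to build site-pattern
    histograms from VCF input under a mappability mask.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    digest,
    stats,
    utils,
    VariantAnnotation,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
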