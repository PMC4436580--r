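Package: papfam
Title: Purple Acid Phosphatase Gene-Family Mining and
    Phosphate-Starvation Response Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for genome-wide identification and characterization of
    plant purple acid phosphatase (PAP) gene families. Implements
    profile-based family mining from a seed alignment (position-specific
    scoring, affine-gap local alignment, Gumbel-calibrated E-values, and
    two-round iterative search), validation of candidates by the five
    conserved metal-binding residue blocks in canonical order with
    splice-model rescue, scanning of upstream regions for the palindromic
    PHR1 binding site (P1BS, GNATATNC), tissue expression summaries (log10
    and per-gene Z-scores), differential transcript accumulation between
    phosphate regimes via a negative-binomial exact test with family-level
    Bonferroni correction, bootstrapped neighbor-joining phylogenies with
    reference-guided group assignment, and co-localization of gene loci
    with QTL intervals. Ships seeded synthetic-data generators so every
    stage is testable against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    withr,
    stats,
    utils,
    methods,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    phangorn
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    rtracklayer,
    jsonlite,
    optparse
Config/testthat/edition: 3
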