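Package: fixscreen
Title: Prioritization of Milk-Fat QTL Genes and Screening for Breed-Group
    Fixed SNP Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for prioritizing candidate milk-fat
    quantitative trait locus (QTL) genes and screening multi-sample
    genotypes for non-synonymous SNPs that are fixed in one breed group
    but variable in the other. Combines set algebra over trait-gene
    annotations, protein-interaction network centrality (hub and
    bottleneck selection by degree and betweenness), intersection with
    differential-expression results, codon-level coding-effect
    annotation of SNPs, and a categorical fixation-pattern classifier
    for two-group cohorts. Ships a synthetic-data generator with ground
    truth so every stage is testable without external downloads, plus
    machine-readable fixtures of the reference result tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    GenomicRanges,
    generics,
    ggplot2,
    igraph,
    IRanges,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
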