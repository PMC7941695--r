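Package: patriline
Title: Y-Chromosome Lineage Analysis from Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for paternal-lineage analysis from Y-chromosome
    sequencing data. Classifies non-recombining Y (NRY) haplogroups from
    variant tables or alignments by scoring marker panels against a rooted
    haplogroup tree and selecting the lineage track with maximal tracking
    rate; genotypes Y-chromosomal short tandem repeats (Y-STRs) from reads
    or indel records by iterative motif extension under standard forensic
    panels; and provides downstream population analyses: haplogroup
    frequency clustering (PCA, pairwise-Fst MDS), two-step phylogeny
    construction with polytomy resolution, scaffolding for Bayesian
    divergence dating, haplotype diversity and AMOVA statistics, Bayesian
    haplogroup prediction from Y-STR profiles, median-joining haplotype
    networks, and TMRCA estimation by the rho and ASD estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
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
    ape,
    phangorn,
    igraph,
    vcfR,
    Rsamtools,
    GenomicRanges,
    IRanges,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
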