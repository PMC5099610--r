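Package: bacpool
Title: Simulation and Analysis of MTP-Based BAC-Pool Targeted Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A simulation-backed toolkit for targeted sequencing of a
    QTL-bearing linkage-group region via minimum-tiling-path (MTP) BAC
    pools. Generates ground-truthed genomes with repeats, SSR markers,
    genes and trait-affecting SNPs; simulates a HindIII clone library,
    HICF-style fingerprinting, FPC contig building and MTP selection;
    builds and screens three-dimensional BAC pools with deconvolution of
    positive wells to clone addresses; simulates paired-end short reads
    and corrected long reads, assembles pools with a greedy overlap
    assembler, scaffolds with long reads, validates by read-back mapping
    with zero-coverage splitting, and anchors BAC-end and marker
    sequences; detects conserved microsynteny blocks against model
    genomes; and performs SNP genotype-growth-trait association
    (t-test, one-way ANOVA, Tukey HSD with compact letter display) and
    efficiency-corrected qPCR expression contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
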