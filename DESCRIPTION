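Package: seedvar
Title: Annotation and Analysis of Genetic Variants in MicroRNA Seed Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A file-based toolkit for annotating genetic variants with respect
    to microRNA gene architecture (pre-miRNA hairpin, mature miRNA, and the
    6mer/7mer seed region), classifying substitutions as transitions or
    transversions, merging adjacent single-nucleotide variants into
    double-nucleotide polymorphisms, detecting seed-switch events in which a
    mutant seed becomes identical to the seed of a different annotated miRNA,
    intersecting polymorphic miRNAs with QTL, fragile-site and host-gene
    annotations, and scanning multi-trait inbred-strain phenotype tables with a
    fixed-effects nested linear model for genotype effects. Ships a
    deterministic synthetic-fixture generator with machine-readable ground
    truth so every step is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    broom,
    optparse
Config/testthat/edition: 3
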