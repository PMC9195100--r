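Package: methTiler
Title: Tiled-Bin Differential Methylation Analysis for Whole-Genome
    Bisulfite Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of whole-genome bisulfite sequencing
    methylomes: exact binomial calling of 5-methylcytosines against a
    chloroplast-estimated non-conversion rate, context-resolved (CG, CHG,
    CHH) detection of differentially methylated cytosines and 100-bp-bin
    differentially methylated regions by Fisher's exact test with
    Benjamini-Hochberg control, allocation of methylation changes to
    tiered genic territories, and integration with replicate-level gene
    expression (DEG classification, metagene methylation profiles by
    expression stratum, qPCR 2^-ddCt relative expression). Ships a
    synthetic WGBS data generator with spiked differentially methylated
    regions and linked expression effects so the whole pipeline is
    exercisable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    data.table,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
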