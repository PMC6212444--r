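Package: diffscan
Title: Genome-Wide Scan for Spatially Varying Selection Between Two
    Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects spatially varying selection between two populations of
    inbred Drosophila strains from multi-sample genotype data. Implements
    site-level Weir & Cockerham F_ST with per-chromosome-arm empirical
    outlier tails, functional-category enrichment of outlier SNPs against a
    small-intron neutral background, gene-level Z_ST scores with SNP-count
    bias correction, GO term enrichment (Fisher, score-based KS, and the
    elim decorrelation algorithm), and transposable-element differentiation
    calibrated on the SNP F_ST distribution. Ships a Balding-Nichols
    synthetic-cohort generator (VCF, masks, gene models, GO DAG, TE calls)
    used for validation and worked examples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    IRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
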