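Package: heteromir
Title: miRNA Inheritance Analysis in Hybrid/Parent Triads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies miRNA expression in maternal/paternal/F1 hybrid
    triads from small RNA-seq counts, identifies differentially expressed
    miRNAs (TPM normalization, replicate t-test, P and fold-change filters),
    classifies each scaled miRNA by the dominance/additivity (D/A) statistic
    into five inheritance modes, and summarizes induced/repressed tallies,
    family-level patterns and cross-hybrid overlaps. Also includes a
    degradome (PARE) cleavage-site caller with plant miRNA-target duplex
    scoring and T-plot export, hypergeometric term enrichment, qPCR
    relative expression by the 2^-ddCt method with Fisher's LSD letters,
    and synthetic-data generators with planted ground truth so the whole
    workflow is testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
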