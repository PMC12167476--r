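Package: crisprdrop
Title: Analysis and Simulation of Pooled CRISPRi Dropout Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for pooled CRISPR-interference (CRISPRi) growth screens
    in which guide RNAs against growth-essential genes drop out of the
    population over time. Collapses raw sequencing reads to per-guide
    spacer counts, median-normalizes counts against the plasmid pool,
    computes per-guide log2 fold changes, scores genes with a top-k guide
    statistic standardized against a non-targeting-control pseudo-gene
    null, and calls hits by z-score together with a Mann-Whitney U test.
    Also classifies long noncoding RNA targets into genomic categories
    (antisense, intergenic, intronic, bidirectional), simulates whole
    screens with known ground truth for calibration and power analysis,
    and analyzes mixed-cell competition assays measured by flow cytometry.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    BiocGenerics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
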