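Package: ervscan
Title: Locus-Level Analysis of Transposable-Element Repression and
    Enhancer Activity in Cloned Mouse Embryos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies transposable-element (TE) loci repressed in embryos
    derived by somatic cell nuclear transfer (SCNT) relative to in vitro
    fertilization (IVF) controls from single-embryo RNA-seq count tables,
    classifies loci as enhancer-like from H3K27ac ChIP/input enrichment
    scored with a sliding-window bin-normalized RPKM, links loci to nearby
    genes by TSS-distance windows with Spearman correlation of condition
    fold changes, and validates putative enhancers with a knockout-comparison
    analysis (expression-based genotype calls, adjacent-gene tests, Mendelian
    chi-square). Includes a seeded synthetic-data generator with planted
    ground truth (negative-binomial per-embryo RNA counts, Poisson ChIP/input
    counts, correlated linked genes) so every stage is testable end to end,
    plus an orchestrating pipeline that emits tabular results and a
    machine-readable JSON report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    DESeq2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
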