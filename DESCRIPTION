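Package: methvalley
Title: DNA Methylation Valleys, Differential Methylation and Tissue
    Specificity from Whole-Genome Bisulfite Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for plant whole-genome bisulfite sequencing
    (WGBS) methylomes built around per-cytosine report files. Detects DNA
    methylation valleys (DMVs) by sliding-window scanning and merging, calls
    differentially methylated regions (DMRs) between tissue groups with a
    Pearson chi-square test on pooled read counts in fixed windows, computes
    global and per-window weighted methylation levels in the CG, CHG and CHH
    contexts, scores tissue specificity of expression with the tau index,
    tests over-representation of gene sets with the hypergeometric
    distribution, and builds strand-aware metagene methylation profiles.
    Includes a fully seeded synthetic data generator (genome, cytosine
    reports, gene annotation, expression matrix, ground-truth manifest) for
    validation and a one-call pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
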