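Package: oncoprofiler
Title: Paired Tumor-Normal Genomic Profiling of Low-Purity Cancers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated analysis pipeline for paired tumor/normal cancer
    genomes with low tumor-cell content, built around depth-ratio tumor purity
    estimation (two-peak formula with a deletion-anchored fallback), a somatic
    SNV/indel filtering cascade against the matched blood sample, consequence
    annotation and mutation rate/spectrum statistics, Poisson driver-gene
    scoring, discordant read-pair clustering into structural-variation signals
    with gene-breakage and interchromosomal fusion calling, BIC-penalized
    copy-number segmentation and classification, and per-gene integrated
    alteration matrices with mutual-exclusivity and cohort comparisons. A
    synthetic-cohort generator with known ground truth (purity, mutation
    rates, drivers, SVs, CNVs) makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    igraph,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
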