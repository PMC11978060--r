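Package: promdyn
Title: Promoter Activity Dynamics from Splice-Junction RNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers per-promoter transcriptional activity from first-intron
    splice-junction read counts in bulk RNA-seq (STAR SJ.out.tab input),
    groups transcripts into promoters by overlapping first exons, classifies
    promoters as major, minor/alternative or inactive, detects
    developmentally dynamic promoters over a time course by cubic polynomial
    regression with FDR control and a goodness-of-fit cutoff, assigns paired
    major/minor dynamics to an eight-category switching taxonomy, and labels
    dynamic promoters as common or organ-specific across organs. Includes a
    negative-binomial junction-count simulator with planted trajectories and
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    DESeq2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
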