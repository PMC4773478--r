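Package: epimr
Title: Integrative Inference of Polycomb-Dependent Master Regulator
    Transcription Factors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrative pipeline for discovering candidate master
    regulator transcription factors that are silenced by Polycomb (PRC2)
    during tumorigenesis. Combines negative-binomial differential
    expression from raw count matrices, H3K27me3 ChIP enrichment
    quantification in TSS-centred windows with spatial pattern
    classification, de novo Polycomb target calling, promoter motif
    enrichment against position weight matrices, TF-centred co-expression
    neighborhoods, gene set enrichment analysis, hypergeometric
    over-representation statistics, and Kaplan-Meier / log-rank survival
    stratification by focal-gene expression. Includes a fully seeded
    synthetic-data generator with planted regulators so every stage of
    the pipeline can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    survival,
    jsonlite,
    yaml,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    fgsea
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
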