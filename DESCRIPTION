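Package: lncscout
Title: Discovery and Multi-Omic Characterization of Novel Long Non-Coding RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A desk-scale, fully testable pipeline for identifying candidate
    long non-coding RNAs (lncRNAs) from an assembled transcriptome and
    characterizing them across omics layers. Implements a strand-aware
    filter cascade (length, annotation overlap, mono-exon distance and
    expression filters, coding potential) with four-way positional
    classification; negative-binomial differential expression with
    median-of-ratios normalization; promoter-methylation and copy-number
    integration; TSS histone-signal profiling and conservation summaries;
    Markov clustering of coexpression graphs with hypergeometric term
    enrichment; GSEA-style running-sum validation against an external
    cohort; and Kaplan-Meier / log-rank screening of prognostic lncRNAs.
    Ships a deterministic synthetic-data generator with a ground-truth
    manifest so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse,
    withr
Config/testthat/edition: 3
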