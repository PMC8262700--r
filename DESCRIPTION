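Package: smallrna
Title: Small RNA Sequencing Quantification, Statistics and Novel miRNA Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for small non-coding RNA sequencing data:
    adapter and quality trimming of FASTQ reads with barcode and UMI handling,
    read collapsing and compression, seed-anchored ungapped mapping against
    genome and ncRNA references, miRNA and isomiR quantification with
    non-templated-addition aware filtering and miRGFF3 export, detection
    filtering and RPM-log2 normalization, differential expression statistics
    (Shapiro-Wilk, Welch t, Wilcoxon-Mann-Whitney, ANOVA, Kruskal-Wallis,
    Benjamini-Hochberg, AUC, Cohen's d), sample embeddings and clustering,
    principal variance component analysis of batch effects, and miRDeep-style
    novel miRNA precursor discovery with hairpin folding and Dicer-consistency
    scoring. Includes a deterministic synthetic-data generator for fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    lme4,
    uwot,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
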