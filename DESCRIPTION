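Package: dmycTargets
Title: Integrative ChIP-Seq and RNA-Seq Identification of Direct Myc Target
    Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies the core set of directly Myc-activated genes
    (including intron-hosted snoRNAs) by integrating ChIP-seq binding data
    with RNA-seq knockdown expression data. Provides peak specificity
    filtering against non-immune IgG and knockdown controls, consensus
    binding-site construction with FDR rescue, TSS-proximity and E-box
    profiling, count normalization and differential calling with
    fold-change classes, expression-aware peak-to-gene assignment with
    intronic snoRNA host substitution, functional-category tabulation,
    gene-set enrichment on ranked expression changes, and a seeded
    synthetic-data generator emulating the four-condition ChIP design and
    replicated knockdown RNA-seq for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
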