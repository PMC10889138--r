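Package: ceRNAflow
Title: Trait-Anchored Competing Endogenous RNA Network Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers lncRNA-miRNA-mRNA competing endogenous RNA (ceRNA)
    triplets from whole-transcriptome count matrices, a genome annotation
    and a physiological trait table. Provides positional classification of
    lncRNA loci (antisense, intergenic, intronic, sense), negative-binomial
    differential expression with median-of-ratios normalization, a weighted
    co-expression core (soft-threshold adjacency, topological overlap,
    module detection, eigengenes, module-trait correlation, hub genes),
    OPLS-DA variable-importance screening of traits, plant-style miRNA
    target scoring, cis/trans lncRNA target prediction, and assembly of
    competitive triplets under a negative miRNA co-expression rule. A
    synthetic-study generator plants every structure the analysis assumes
    so the full pipeline is verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
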