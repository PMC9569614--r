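Package: bsaseq
Title: Bulked Segregant Analysis QTL Mapping with RNA-Seq Integration
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Maps quantitative trait loci from bulked segregant sequencing
    (BSA-Seq) of an F2 cross using the SNP-index and delta(SNP-index)
    statistics with sliding-window smoothing and permutation-derived
    significance thresholds, classifies candidate-region variants at the
    codon level (synonymous, non-synonymous, stop-gain, stop-loss), calls
    differentially expressed genes from RNA-Seq counts with a minimal
    negative-binomial Wald test, and intersects the two evidence layers to
    nominate candidate genes. Includes a seeded simulator of an F2
    population (Haldane map function, additive QTL, pooled short-read
    allele depths, gene models and NB RNA-Seq counts) so the entire
    pipeline is testable at desk scale without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation,
    graphics,
    grDevices,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Genetics, QTL, Sequencing, DifferentialExpression, Software
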