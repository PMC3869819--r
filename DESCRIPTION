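Package: scamprSeq
Title: Rare Mutation Detection in Pooled Amplicon Sequencing of Mutagenized
    Populations
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects rare EMS-induced point mutations in multidimensionally
    pooled amplicon sequencing data from mutagenized (TILLING) populations,
    including allopolyploids. Provides the tri-dimensional (column, row,
    plate) pooling design with encoding and decoding of pool triples to
    candidate lines, quality-filtered per-base allele counting from SAMtools
    mpileup text, per-pool substitution-frequency computation, one-sided
    t-test candidate calling with three-pool coincidence and homeologous-SNP
    discrimination, PARSESNP-style effect annotation, TILLING population
    statistics (mutation density with amplicon-edge exclusion, per-genome
    extrapolation, substitution spectrum, per-line mutation distribution),
    and a seeded simulator of pooled amplicon base counts for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    Biostrings,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    rtracklayer,
    GenomicRanges,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
biocViews: Sequencing, VariantDetection, Genetics, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
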