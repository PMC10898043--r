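Package: rrmp
Title: In Silico Reduced Representative Methylome Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for reduced representative
    methylome profiling (RRMP), a library-preparation strategy that depletes
    AT-rich fragments by restriction digestion after enzymatic C-to-T
    conversion, thereby enriching CpG-dense regulatory sequence. The package
    simulates genomes with CpG-island architecture, cfDNA and sheared-gDNA
    libraries with per-molecule CpG methylation, strand-resolved conversion
    and incomplete-conversion filtering; scans converted sequence for
    restriction recognition sites and applies 1-cut (MseI) or 4-cut
    (MseI, MluCI, SspI, PsiI) in silico digestion, including depletion of
    external converted FASTQ reads; and provides downstream analytics:
    element capture at a combined-coverage threshold, downsampling
    saturation curves, per-CpG concordance, differentially methylated region
    calling with Fisher exact tests, histone-peak association, and a
    leave-one-out logistic-regression cfDNA cancer classifier with ROC/AUC
    reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    glmnet,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
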