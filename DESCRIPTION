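Package: epiFST
Title: Analysis of Epigenetic Variance and an FST-Like Statistic for
    Histone Modification Peaks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Partitions normalized epigenetic peak-density variation within
    and between species with a one-way random-effects analysis of variance
    (ANEVA), computes a per-peak and per-gene FST-like differentiation
    statistic (epi-FST) with permutation significance, and relates
    epigenetic divergence to genomic context: proximity of peaks to
    transcription start sites, SNP density in sliding windows, windowed
    principal-component distances between species, and over-representation
    of differentially expressed genes among top-ranked genes. Includes a
    synthetic-data generator with known variance components so every
    analysis is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3.0),
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
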