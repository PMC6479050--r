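Package: bindexpr
Title: Integrating Transcription-Factor Binding with Differential Expression
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Integration of ChIP-seq binding with RNA-seq differential
    expression: partitioning of paired peak sets into co-occupancy classes,
    genomic-distribution annotation over gene features, binned signal
    profiling around binding sites, exponential distance-decay
    regulatory-potential scoring, Kolmogorov-Smirnov inference of activating
    and repressive function against a static-gene background, direct-target
    calling by rank product, and peak-to-gene distance comparisons.  Includes
    a seeded synthetic-study generator that plants direct targets with known
    truth, plus readers and writers for BED, narrowPeak, refFlat, bedGraph
    and DESeq2-style expression tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
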