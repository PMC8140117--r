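Package: syncliptic
Title: Compartment-Specific CLIP-seq Peak Enrichment and RNA Stability
    Analysis Without Replicates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies compartment-specific RNA-binding-protein peaks from
    a two-sample CLIP-seq design without replicates, using MA-plot LOESS
    normalization on TMM effective library sizes, a common negative-binomial
    dispersion estimated from the central MA cloud, and a per-peak
    likelihood-ratio test with LOESS-adjusted offsets. Also provides the
    downstream machinery around such screens: peak feature classification
    against a GTF gene model, fixed-width motif windows and annotation-matched
    zero-coverage background sequences, mRNA-stability time-course testing and
    correlation-distance clustering, over-representation and association
    tests, label-free proteomics statistics, and seeded synthetic-data
    generators for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    methods,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    edgeR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
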