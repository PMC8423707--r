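Package: cryptex
Title: Cryptic Exon Discovery from Splice-Junction Counts and Quantitative
    hnRNP K Mislocalisation Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects cryptic and skiptic cassette-exon events from per-sample
    splice-junction read counts. Junctions are grouped into overlapping
    clusters, per-cluster differential junction usage between two conditions
    is tested with a Dirichlet-multinomial likelihood-ratio test, and
    cassette topologies within significant clusters are quantified by
    percent-spliced-in (PSI) and classified as cryptic, skiptic, included,
    skipped or weak. Downstream feature modules compute reading-frame
    preservation, mean per-base conservation, k-mer presence enrichment
    between exon sets, and a downregulation-bias test against an
    expression-matched null gene set. A separate module implements a
    quantitative digital-pathology framework for neuronal hnRNP K
    mislocalisation: random non-overlapping tile sampling, per-case density
    and mislocalisation metrics, age-ordered cumulative mislocalisation
    curves and cohort summaries. Seeded synthetic-data generators emulate
    every input so the full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3.0)
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
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: AlternativeSplicing, RNASeq, DifferentialSplicing, Software
RoxygenNote: 7.3.3
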