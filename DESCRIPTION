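Package: spliceclip
Title: Splice-Site Cross-Link Occupancy and Differential Splicing Analysis
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of individual-nucleotide resolution crosslinking
    (iCLIP) reverse-transcription stop data around intronic 3' splice
    sites, built around the comparison of a wild-type and a mutant
    splicing-factor condition. Implements 3' splice-site occupancy
    saturation analysis (rolling-quantile curves with a plateau
    estimate), metagene cross-link profiles, deterministic binding
    clusters C1-C10 with cluster-switch detection, hexamer and
    trinucleotide motif statistics against a resampling null,
    percent-spliced-in (PSI) differential-splicing calls with a
    Beta-binomial Bayes-factor surrogate, cohort-level splicing tests,
    and binding-splicing-expression integration statistics. A
    synthetic-data generator emulates the statistical structure of the
    iCLIP and RNA-seq derived inputs so the whole pipeline runs without
    external data.
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
    Biostrings,
    SummarizedExperiment,
    data.table,
    zoo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
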