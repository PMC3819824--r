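Package: chromaccess
Title: Quantitative Modeling of Chromatin Accessibility from Chromatin
    Features in DNase I Hypersensitive Sites
Version: 0.1.0
Authors@R: person("chromaccess", "developers", role = c("aut", "cre"),
    email = "chromaccess@example.org")
Description: Tools to quantify how histone-modification and
    transcription-factor ChIP-seq signals relate to chromatin
    accessibility measured by DNase-seq within DNase I hypersensitive
    sites (DHSs). Provides BED/bedGraph/wiggle ingestion, per-region
    signal aggregation (maximum or average), peak localization
    statistics, support vector regression and linear models under
    k-fold cross-validation with the square-root coefficient of
    determination as prediction power, exhaustive feature-subset
    redundancy analysis with hypergeometric enrichment of top
    combinations, sample-size curves, and a synthetic data generator so
    the whole pipeline is testable without external tracks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    quadprog,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
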