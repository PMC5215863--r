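Package: countseg
Title: Chromatin-State Annotation from Binned Sequencing Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: De novo chromatin-state annotation from multivariate sequencing
    count tracks with a hidden Markov model whose emissions are negative
    binomial or Poisson-lognormal, fitted by Baum-Welch with count-grouping
    and library-size correction. Includes read binning with fragment-shift
    estimation, segmentation output, recall/FDR/AUC benchmarking against
    reference region sets, transcription-factor enrichment and co-binding
    statistics, GWAS trait enrichment with coverage-controlled subsampling,
    and a fully seeded synthetic-data generator, plus a command-line
    front-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    optparse,
    pracma,
    purrr,
    Rcpp,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
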