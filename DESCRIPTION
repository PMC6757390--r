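Package: haarCNV
Title: Wavelet-Compressed Forward-Backward Gibbs Sampling for Copy-Number
    Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Fully Bayesian segmentation of genome-scale read-depth signals
    into copy-number states using a Gaussian-emission hidden Markov model
    sampled by Forward-Backward Gibbs sampling over dynamically compressed
    data. Compression blocks are the discontinuities of a Haar wavelet
    regression at the universal threshold, rederived each sweep from the
    smallest sampled emission variance. The package provides the linear-time
    in-place maxlet and Haar boundary transforms, a breakpoint array with
    capped jump pointers for expected-logarithmic block queries, a
    cell-partitioned integral array for constant-time block sufficient
    statistics, run-length compressed posterior state counts, a two-track
    differential-coverage simulator, and a command-line caller emitting BED
    segments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    optparse,
    rtracklayer,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
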