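Package: bruuv
Title: Active TSS and UV-Enhancement Peak Calling from UV-Redistributed
    Nascent RNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls active transcription start sites (TSSs) and UV-enhanced
    (UVE) regions, including putative enhancers, from BruUV-seq data:
    nascent RNA sequencing after UVC irradiation, which blocks transcription
    elongation at random DNA lesions and redistributes read density toward
    5' ends while stabilizing labile transcripts such as eRNA. Provides a
    two-state monotone hidden Markov model for TSS activity calling on
    quantile- and gamma-z-normalized TSS windows, a beta-binomial hidden
    Markov model segmenting paired mock/UV coverage into UV-repressed and
    UV-enhanced states, supporting signal transformations (quantile
    normalization, gamma-equivalent z-scores, common-depth scaling, wavelet
    denoising), descriptive profile/fold-change/correlation analyses, and a
    mechanistic simulator of paired mock/UV tracks with ground truth based
    on a Poisson transcription-blocking lesion model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
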