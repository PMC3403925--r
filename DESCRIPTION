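Package: mdaqc
Title: Uniformity and Fidelity Assessment of Whole-Genome-Amplified DNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to assess how uniformly and faithfully multiple
    displacement amplification (MDA) reproduces a genome, using two-channel
    array-CGH probe ratios as the readout.  Provides probe-level log2-ratio
    computation with median normalization, derivative log-ratio spread (DLRS)
    quality estimation, circular binary segmentation (CBS) with permutation
    significance, fold-change threshold tables, pairwise Kolmogorov-distance
    and Phi-correlation consistency matrices, calling and intersection of
    consistently under-amplified regions with GC-content summaries, TaqMan
    style delta-delta-Ct relative copy-number estimation, and bidirectional
    Sanger-read concordance screening for amplification-induced mutations.
    A seed-reproducible synthetic-data generator emulates MDA amplification
    bias (GC-dependent and chromosome-end under-amplification, injected copy
    number variants, replicate noise) so the whole pipeline can be exercised
    without array data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    methods,
    Rcpp,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite, optparse, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
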