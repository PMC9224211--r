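Package: isobench
Title: Benchmarking Compositional Segmentation on Simulated Isochore Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates DNA sequences built from known GC-homogeneous domains drawn
    from the five classical isochore families (L1, L2, H1, H2, H3), with either
    equal-length domain structure or variable-length domains sampled from a
    power law. Two competing compositional segmentation algorithms are provided:
    a fixed-window classify-and-merge segmenter (100-kb windows classified into
    isochore families, same-family neighbours merged) and a recursive binary
    segmenter that splits at the point of maximal Jensen-Shannon divergence and
    halts via a dynamic, Monte-Carlo calibrated threshold depending on segment
    length and GC composition. Predictions are scored against the known domain
    structure with a boundary-matching rule (both boundaries within a fraction
    of the predicted domain length) yielding sensitivity, precision and Jaccard
    index, and a benchmark driver aggregates pooled and per-setting statistics
    including Wilcoxon rank-sum comparisons between algorithms.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
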