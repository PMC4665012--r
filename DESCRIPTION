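Package: panelforge
Title: Design and Evaluation of Viral Targeted Sequence Capture Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Condenses large, redundant collections of viral genome sequences
    into compact target panels for hybridization-based sequence capture, and
    evaluates capture performance from read alignments. Implements exhaustive
    1-bp sliding-window k-mer decomposition of genome-neighbor sequences,
    glocal affine-gap percent-identity scoring, greedy centroid clustering at a
    fixed identity threshold, merging and excision of divergent spans, a
    long-sequence clustering mode for very large strain collections, taxonomic
    and host-similarity filtering of panel entries, DUST-style low-complexity
    hard-masking, naive probe tiling with 0-bp and 100-bp offset coverage
    metrics, and pre/post-capture comparison statistics (breadth and depth of
    coverage, gap statistics, start-site read deduplication, fold enrichment in
    viral read fraction, and divergent-contig recovery). A seeded synthetic
    data module generates strain clouds of controlled divergence and pre/post
    capture alignment sets with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    stringr,
    generics,
    withr,
    jsonlite,
    yaml,
    optparse,
    ggplot2,
    Biostrings,
    IRanges,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Rsamtools
Config/testthat/edition: 3
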