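Package: occlean
Title: Overlapping Community Detection with Noisy Pairwise Constraint Cleaning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Semi-supervised overlapping community detection under noisy
    pairwise supervision. Implements speaker-listener label propagation
    (SLPA), its pairwise-constrained variant (PC-SLPA), and an active
    constrained pipeline (AC-SLPA) in which must-link / cannot-link
    constraints from an imperfect oracle are filtered by outlier detection
    before guiding propagation. Includes an LFR-style overlapping benchmark
    generator, topological pair-feature extraction (SimRank, random-walk
    skip-gram embeddings), outlier detectors (isolation forest, one-class
    SVM, local outlier factor, plain and L1-sparse autoencoders), and
    evaluation metrics (overlapping NMI, ROC-AUC of noise detection,
    Kolmogorov-Smirnov comparison of community-size distributions).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Matrix,
    e1071,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
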