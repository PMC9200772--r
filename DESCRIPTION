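Package: frcellmatch
Title: Cell Type Matching Across Single-Cell Experiments with the
    Friedman-Rafsky Test
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reference-based cell type matching for single-cell RNA-seq
    clusters built on the Friedman-Rafsky multivariate runs test. A minimum
    spanning tree is grown on pooled query and reference cells in marker-gene
    space and the number of same-sample subtrees ("runs") is compared against
    its permutation null to decide whether two clusters are draws from the
    same expression distribution. The test is wrapped in two matching
    schemes: iterative subsampled cell-to-cluster matching with p-value
    max-updating, and cluster-to-cluster matching by median p-value, both
    with Benjamini-Hochberg correction and an "unassigned" call for query
    cells or clusters with no counterpart in the reference (novel cell type
    detection). Includes cross-platform normalization (gene-wise min-max
    rescaling plus cluster-summary weighting to suppress plate-based
    background noise), a scale-invariant cosine distance option, multivariate
    normal simulation scenarios for power and calibration studies, a
    marker-structured synthetic atlas generator with platform-style
    distortions, and a leave-one-cluster-out protocol for validating novelty
    detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    parallel,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
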