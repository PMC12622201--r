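Package: psrt
Title: Persistent Stanley-Reisner Invariants for Point Clouds and Protein Mutations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Computes persistent Stanley-Reisner invariants -- facet-ideal
    persistence barcodes, f-vector curves and h-vectors -- over Vietoris-Rips
    and alpha-complex filtrations of labeled 3-D point clouds.  Provides an
    element- and site-specific featurization of protein point mutations
    (mutation-site versus neighborhood atom sets under a modified Euclidean
    metric) that concatenates multiscale facet-ideal and f-vector statistics
    into a commutative-algebra embedding, together with downstream
    gradient-boosted-tree (CATree) and feed-forward-network (CANet) learners
    and evaluation metrics for mutation-effect prediction tasks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    pROC,
    stats,
    utils,
    withr,
    xgboost
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
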