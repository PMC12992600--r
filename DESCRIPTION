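Package: adaptdr
Title: Adaptive Neighbourhood Selection and Intrinsic Dimension for
    Nonparametric Dimensionality Reduction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Joint estimation of the intrinsic dimension of a point cloud
    and of locally adaptive nearest-neighbour neighbourhood sizes via a
    binomial likelihood estimator combined with a likelihood-ratio scan for
    local homogeneity of the sampling density (the ABIDE procedure).  The
    estimated per-point neighbourhood sizes and intrinsic dimension drive
    adaptive versions of three neighbourhood-based embedding methods:
    locally linear embedding, Laplacian spectral embedding with k-means
    clustering, and a fuzzy simplicial (UMAP-style) embedding, together
    with an out-of-sample projection rule, a synthetic manifold benchmark
    generator, and a clustering/supervised evaluation harness.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Matrix,
    methods,
    nnet,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
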