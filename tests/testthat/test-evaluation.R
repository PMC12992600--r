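# Clustering indices are checked against exhaustive pair-counting and
# direct entropy computations, and (for the adjusted Rand index) against
# an established independent implementation.

test_that("perfect and degenerate agreement cases", {
  truth <- c(0, 0, 1, 1, 2, 2)
  m <- clustering_metrics(truth, c(5, 5, 9, 9, 7, 7))  # relabelled truth
  expect_equal(m$ari, 1)
  expect_equal(m$v_measure, 1)
  # one predicted cluster over >= 2 classes
  m1 <- clustering_metrics(truth, rep(1, 6))
  expect_equal(m1$homogeneity, 0)
  expect_equal(m1$completeness, 1)
  expect_equal(m1$v_measure, 0)
  # the crossed worked example
  expect_equal(clustering_metrics(c(0, 0, 1, 1), c(0, 1, 0, 1))$ari,
               -0.5)
  expect_error(clustering_metrics(1:3, 1:4), "mismatch")
})

test_that("indices agree with exhaustive oracles on all partitions of 6
           points", {
  parts <- all_partitions(6)
  expect_length(parts, 203)           # Bell(6)
  set.seed(51)
  idx <- sample(length(parts))
  # every partition against a rotating subset of others (full cross of
  # 203^2 pairs is redundant; each partition appears in several pairs)
  for (r in seq_along(parts)) {
    truth <- parts[[r]]
    pred <- parts[[idx[r]]]
    m <- clustering_metrics(truth, pred)
    expect_equal(m$ari, pair_counting_ari(truth, pred),
                 tolerance = 1e-12)
    o <- entropy_metrics_oracle(truth, pred)
    expect_equal(m$homogeneity, o$homogeneity, tolerance = 1e-12)
    expect_equal(m$completeness, o$completeness, tolerance = 1e-12)
    expect_equal(m$v_measure, o$v_measure, tolerance = 1e-12)
  }
})

test_that("adjusted Rand index matches the mclust implementation", {
  set.seed(52)
  for (r in 1:25) {
    truth <- sample(1:4, 30, replace = TRUE)
    pred <- sample(1:3, 30, replace = TRUE)
    expect_equal(clustering_metrics(truth, pred)$ari,
                 mclust::adjustedRandIndex(truth, pred),
                 tolerance = 1e-12)
  }
})

test_that("v-measure is the harmonic mean of its components", {
  set.seed(53)
  for (r in 1:20) {
    truth <- sample(1:3, 40, replace = TRUE)
    pred <- sample(1:5, 40, replace = TRUE)
    m <- clustering_metrics(truth, pred)
    h <- m$homogeneity; c_ <- m$completeness
    if (h + c_ > 0)
      expect_equal(m$v_measure, 2 * h * c_ / (h + c_), tolerance = 1e-12)
  }
})

test_that("k-means harness: separation, rotation invariance", {
  bl <- make_blobs(n_per = 40, sep = 20, D = 3, seed = 54)
  m <- kmeans_evaluate(bl$X, bl$labels, seed = 2)
  expect_equal(m$ari, 1)
  Q <- random_rotation(3, seed = 55)
  mq <- kmeans_evaluate(bl$X %*% Q, bl$labels, seed = 2)
  expect_equal(mq$ari, m$ari)
  expect_equal(mq$homogeneity, m$homogeneity)
})

test_that("grid-search harness sweeps, flags the comparator, records
           failures", {
  bl <- make_blobs(n_per = 35, sep = 15, D = 4, seed = 56)
  ## far-apart blobs leave some fixed-k graphs disconnected: the sweep
  ## must warn-and-continue, not abort
  tab <- suppressWarnings(
    grid_search_baseline(bl$X, bl$labels, method = "lle",
                         k_grid = c(5, 10, 70, 15), d_grid = 2,
                         seed = 1, k_ref = 11, d_ref = 2))
  expect_equal(nrow(tab), 4)
  expect_true(any(tab$comparator))
  expect_equal(tab$k[tab$comparator], 10)   # closest to k_ref = 11
  expect_true(is.na(tab$ari[tab$k == 70]))  # k = n: cell fails, sweep not
  expect_match(tab$error[tab$k == 70], "insufficient")
  expect_false(anyNA(tab$ari[tab$k != 70]))
  # degeneration consistency: a grid cell equals the direct fixed-k run
  direct <- suppressWarnings(lle_star(bl$X, d_proj = 2, n_neighbors = 10))
  m_direct <- kmeans_evaluate(direct$embedding, bl$labels, seed = 1)
  expect_equal(tab$ari[tab$k == 10], m_direct$ari, tolerance = 1e-12)
})

test_that("supervised probe: separable classes, permutation null", {
  ## a connected planar cloud with two gapped class bands: the embedding
  ## recovers the plane, so the bands stay linearly separable
  pl <- make_plane(240, D = 5, seed = 57)
  keep <- abs(pl$latent[, 1]) > 0.25
  X <- pl$X[keep, , drop = FALSE]
  labels <- as.integer(pl$latent[keep, 1] > 0)
  pr <- supervised_probe(X, labels, folds = 3, seed = 5, d_proj = 2,
                         n_neighbors = 8)
  expect_equal(pr$accuracy, 1)
  expect_equal(pr$f1_macro, 1)
  expect_equal(nrow(pr$per_fold), 3)
  # label permutation collapses accuracy to chance level
  set.seed(58)
  perm_labels <- sample(labels)
  pr0 <- supervised_probe(X, perm_labels, folds = 3, seed = 5,
                          d_proj = 2, n_neighbors = 8)
  expect_lt(pr0$accuracy, 0.75)
  expect_gt(pr0$accuracy, 0.25)
})

test_that("stratified folds never produce single-class folds", {
  labels <- rep(1:3, times = c(30, 6, 9))
  fold <- adaptdr:::stratified_folds(labels, 3, seed = 1)
  for (f in 1:3)
    expect_equal(sort(unique(labels[fold == f])), 1:3)
})
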