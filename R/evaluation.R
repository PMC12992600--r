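#' External clustering agreement metrics
#'
#' Adjusted Rand index, homogeneity, completeness and V-measure computed
#' from the contingency table between a reference partition and a
#' predicted one.  Homogeneity is `1 - H(C|K) / H(C)` (each cluster
#' contains members of a single class), completeness is
#' `1 - H(K|C) / H(K)` (members of a class share a cluster), and the
#' V-measure is their harmonic mean.  All are invariant to relabelling of
#' the predicted clusters; the adjusted Rand index ranges over
#' `[-1, 1]`, the others over `[0, 1]`.
#'
#' @param truth reference labels.
#' @param pred predicted labels (same length).
#' @return class `metrics_report`: list with `ari`, `homogeneity`,
#'   `completeness`, `v_measure`.
#' @export
#' @examples
#' clustering_metrics(c(0, 0, 1, 1), c(1, 1, 2, 2))$ari  # 1
clustering_metrics <- function(truth, pred) {
  if (length(truth) != length(pred))
    stop("label length mismatch")
  n <- length(truth)
  if (n < 2L) stop("need at least 2 points")
  ct <- table(truth, pred)
  ## adjusted Rand index
  sum_comb <- sum(choose(ct, 2))
  a_comb <- sum(choose(rowSums(ct), 2))
  b_comb <- sum(choose(colSums(ct), 2))
  expected <- a_comb * b_comb / choose(n, 2)
  max_index <- (a_comb + b_comb) / 2
  ari <- if (max_index == expected) {
    if (sum_comb == expected) 1 else 0
  } else (sum_comb - expected) / (max_index - expected)
  ## entropy-based metrics (natural log; ratios are base-invariant)
  p <- ct / n
  pr <- rowSums(p); pc <- colSums(p)
  H_C <- -sum(pr[pr > 0] * log(pr[pr > 0]))
  H_K <- -sum(pc[pc > 0] * log(pc[pc > 0]))
  nz <- p > 0
  H_C_given_K <- -sum(p[nz] * log(sweep(p, 2L, pc, "/")[nz]))
  H_K_given_C <- -sum(p[nz] * log(sweep(p, 1L, pr, "/")[nz]))
  homogeneity <- if (H_C == 0) 1 else 1 - H_C_given_K / H_C
  completeness <- if (H_K == 0) 1 else 1 - H_K_given_C / H_K
  v <- if (homogeneity + completeness == 0) 0 else
    2 * homogeneity * completeness / (homogeneity + completeness)
  structure(list(ari = ari, homogeneity = homogeneity,
                 completeness = completeness, v_measure = v),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  flds <- Filter(function(v) is.numeric(v) && length(v) == 1L, unclass(x))
  cat(paste(sprintf("%s = %.3f", names(flds), unlist(flds)),
            collapse = ", "), "\n")
  invisible(x)
}

#' K-means evaluation of an embedding against reference labels
#'
#' Runs seeded k-means (`nstart` restarts) on the embedding with as many
#' clusters as there are reference classes, then scores the result with
#' [clustering_metrics()].  Rows with missing coordinates (points left
#' unembedded by a disconnected graph) are dropped from both the
#' embedding and the labels.
#'
#' @param E an `embedding` or a plain coordinate matrix.
#' @param truth reference labels.
#' @param seed RNG seed for the restarts.
#' @param nstart number of k-means restarts.
#' @return a `metrics_report` with the k-means `inertia` attached.
#' @export
kmeans_evaluate <- function(E, truth, seed = NULL, nstart = 10L) {
  Y <- if (inherits(E, "embedding")) E$Y else as.matrix(E)
  if (nrow(Y) != length(truth)) stop("label length mismatch")
  ok <- stats::complete.cases(Y)
  Y <- Y[ok, , drop = FALSE]
  truth <- truth[ok]
  g <- length(unique(truth))
  if (!is.null(seed)) set.seed(seed)
  km <- kmeans(Y, centers = g, nstart = nstart, iter.max = 100L)
  rep <- clustering_metrics(truth, km$cluster)
  rep$inertia <- km$tot.withinss
  rep$n_used <- sum(ok)
  rep
}

#' Grid-search baseline over fixed neighbourhood sizes and dimensions
#'
#' Runs the non-adaptive version of an embedder (fixed `k` for every
#' point) at every grid point and scores each embedding by seeded
#' k-means against the reference labels.  This is the comparison harness
#' for the adaptive methods: the cell closest to (median adaptive
#' neighbourhood size, estimated dimension) is flagged as the
#' summary-statistic comparator when those values are supplied.
#' Failures of individual cells are recorded in the `error` column and
#' the sweep continues.
#'
#' @param X data matrix.
#' @param truth reference labels.
#' @param method one of `"lle"`, `"spectral"`, `"umap"`.
#' @param k_grid neighbourhood sizes to sweep.
#' @param d_grid embedding dimensions to sweep.
#' @param seed RNG seed used for every stochastic stage.
#' @param k_ref,d_ref optional adaptive summary values used to flag the
#'   comparator cell.
#' @param ... further arguments passed to the underlying embedder.
#' @return data frame with one row per grid cell: `method`, `k`, `d`,
#'   the four clustering metrics, `comparator`, `error`.
#' @export
grid_search_baseline <- function(X, truth, method = c("lle", "spectral",
                                                      "umap"),
                                 k_grid = seq(5L, 50L, by = 5L),
                                 d_grid = 2L, seed = 1L, k_ref = NULL,
                                 d_ref = NULL, ...) {
  method <- match.arg(method)
  grid <- expand.grid(k = as.integer(k_grid), d = as.integer(d_grid))
  res <- lapply(seq_len(nrow(grid)), function(r) {
    k <- grid$k[r]; d <- grid$d[r]
    out <- tryCatch({
      emb <- switch(method,
        lle = lle_star(X, d_proj = d, n_neighbors = k, ...)$embedding,
        spectral = sc_star(X, n_clusters = length(unique(truth)),
                           d_proj = d, n_neighbors = k,
                           seed = seed, ...)$embedding,
        umap = umap_star(X, d_proj = d, n_neighbors = k, seed = seed,
                         ...)$embedding)
      m <- kmeans_evaluate(emb, truth, seed = seed)
      data.frame(method = method, k = k, d = d, ari = m$ari,
                 homogeneity = m$homogeneity,
                 completeness = m$completeness, v_measure = m$v_measure,
                 error = NA_character_)
    }, error = function(e)
      data.frame(method = method, k = k, d = d, ari = NA_real_,
                 homogeneity = NA_real_, completeness = NA_real_,
                 v_measure = NA_real_, error = conditionMessage(e)))
    out
  })
  res <- do.call(rbind, res)
  res$comparator <- FALSE
  if (!is.null(k_ref) && !is.null(d_ref)) {
    i <- which.min(abs(res$k - k_ref) + 1e6 * abs(res$d - d_ref))
    res$comparator[i] <- TRUE
  }
  res
}

## stratified fold assignment: shuffle within class, deal round-robin
stratified_folds <- function(labels, folds, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

macro_f1 <- function(truth, pred) {
  classes <- unique(truth)
  f1 <- vapply(classes, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    if (2 * tp + fp + fn == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1)
}

#' Cross-validated supervised probe of an adaptive embedding
#'
#' Stratified m-fold cross-validation of the full supervised pipeline:
#' the adaptive locally linear embedding is fitted on the training folds,
#' held-out points are projected with the out-of-sample rule, and an
#' unpenalised multinomial logistic regression fitted on the training
#' embedding predicts the held-out classes.  Reports accuracy and
#' macro-averaged F1 so that the score reflects the quality of the
#' dimensionality reduction rather than classifier regularisation.
#'
#' @param X data matrix.
#' @param labels class labels.
#' @param folds number of cross-validation folds (>= 2).
#' @param seed RNG seed (fold assignment).
#' @param d_proj optional fixed embedding dimension.
#' @param ... further arguments passed to [lle_star()].
#' @return class `metrics_report` with `accuracy`, `f1_macro` and the
#'   per-fold table `per_fold`.
#' @export
supervised_probe <- function(X, labels, folds = 3L, seed = 1L,
                             d_proj = NULL, ...) {
  X <- check_data_matrix(X)
  folds <- as.integer(folds)
  if (folds < 2L) stop("folds must be >= 2")
  labels <- as.factor(labels)
  fold <- stratified_folds(labels, folds, seed = seed)
  per <- lapply(seq_len(folds), function(f) {
    tr <- fold != f
    model <- lle_star(X[tr, , drop = FALSE], d_proj = d_proj, ...)
    Y_tr <- model$embedding$Y
    ok <- stats::complete.cases(Y_tr)
    df <- data.frame(y = labels[tr][ok])
    df <- cbind(df, as.data.frame(Y_tr[ok, , drop = FALSE]))
    clf <- nnet::multinom(y ~ ., data = df, decay = 0, trace = FALSE,
                          maxit = 500L, MaxNWts = 10000L)
    Y_te <- predict.lle_star(model, X[!tr, , drop = FALSE])
    te_ok <- stats::complete.cases(Y_te)
    nd <- as.data.frame(Y_te[te_ok, , drop = FALSE])
    colnames(nd) <- colnames(df)[-1L]
    pred <- predict(clf, newdata = nd)
    truth <- labels[!tr][te_ok]
    data.frame(fold = f, accuracy = mean(pred == truth),
               f1_macro = macro_f1(as.character(truth),
                                   as.character(pred)))
  })
  per <- do.call(rbind, per)
  structure(list(accuracy = mean(per$accuracy),
                 f1_macro = mean(per$f1_macro), per_fold = per,
                 folds = folds, seed = seed),
            class = "metrics_report")
}
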