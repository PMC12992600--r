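#' Laplacian spectral embedding of a symmetric neighbourhood graph
#'
#' Embeds the vertices of a symmetric weighted graph using the
#' symmetric-normalised Laplacian `L = I - D^{-1/2} W D^{-1/2}`: the
#' eigenvectors of the `d_proj` smallest eigenvalues after the trivial
#' first one.  Eigenvalues of the normalised Laplacian always lie in
#' `[0, 2]`.  Rows can optionally be normalised to unit length before
#' downstream clustering.
#'
#' @param G a symmetric `weight_graph` (see [symmetrize()]).
#' @param d_proj number of embedding coordinates.
#' @param row_normalize normalise embedding rows to unit Euclidean norm.
#' @return an `embedding` with the retained `eigenvalues`.
#' @export
spectral_embed <- function(G, d_proj, row_normalize = FALSE) {
  stopifnot(inherits(G, "weight_graph"))
  if (!G$symmetrized) stop("graph must be symmetrized first")
  d_proj <- as.integer(d_proj)
  if (d_proj < 1L) stop("d_proj must be >= 1")
  deg <- Matrix::rowSums(G$W)
  if (any(deg <= 0))
    stop("isolated vertices: ",
         paste(utils::head(which(deg <= 0), 10L), collapse = ", "))
  Dh <- Diagonal(x = 1 / sqrt(deg))
  L <- Diagonal(G$n) - Dh %*% G$W %*% Dh
  L <- Matrix::forceSymmetric((L + Matrix::t(L)) / 2)
  eig <- bottom_eigs(L, d_proj + 1L)
  sel <- 2L:(d_proj + 1L)
  Y <- eig$vectors[, sel, drop = FALSE]
  if (row_normalize) {
    nrm <- sqrt(rowSums(Y^2))
    nrm[nrm == 0] <- 1
    Y <- Y / nrm
  }
  new_embedding(Y, "spectral_star", eigenvalues = eig$values[sel],
                centered = FALSE, unit_cov = FALSE,
                row_normalized = row_normalize)
}

#' Adaptive spectral clustering
#'
#' Estimates the intrinsic dimension and adaptive neighbourhood sizes,
#' builds the adaptive adjacency, symmetrizes it by edge union, embeds in
#' `d_star` dimensions via the normalised graph Laplacian, and runs
#' k-means on the spectral coordinates.  If the symmetrized graph is
#' disconnected, components are first joined by their shortest
#' inter-component edge (logged), since spectral embedding of a
#' disconnected graph mixes component indicators.  Passing `n_neighbors`
#' degenerates to standard fixed-k spectral clustering.
#'
#' @param X data matrix.
#' @param n_clusters number of clusters (>= 2).
#' @param d_proj embedding dimension; defaults to the rounded intrinsic
#'   dimension estimate.
#' @param n_neighbors optional fixed neighbourhood size (baseline mode;
#'   requires `d_proj`).
#' @param seed seed for the k-means restarts.
#' @param nstart number of k-means restarts.
#' @param row_normalize passed to [spectral_embed()].
#' @param tau,alpha,k_min,k_max,tol,max_iter parameters passed to
#'   [abide()].
#' @return list of class `sc_star` with `clusters` (class
#'   `cluster_assignment`: integer `labels` in `1..n_clusters`,
#'   `n_clusters`, `inertia`), `embedding`, `estimate`, `neighborhood`,
#'   `graph`.
#' @export
sc_star <- function(X, n_clusters, d_proj = NULL, n_neighbors = NULL,
                    seed = NULL, nstart = 10L, row_normalize = FALSE,
                    tau = 0.5, alpha = 0.01, k_min = 3L, k_max = NULL,
                    tol = 1e-3, max_iter = 50L) {
  X <- check_data_matrix(X)
  n_clusters <- as.integer(n_clusters)
  if (n_clusters < 2L) stop("n_clusters must be >= 2")
  n <- nrow(X)
  k_max <- as.integer(k_max %||% min(n - 1L, 100L))
  if (is.null(n_neighbors)) {
    fit <- abide(X, tau = tau, alpha = alpha, k_min = k_min,
                 k_max = k_max, tol = tol, max_iter = max_iter)
    nt <- fit$neighbors; K <- fit$neighborhood; est <- fit$estimate
    d_proj <- as.integer(d_proj %||% est$d_star)
  } else {
    if (is.null(d_proj))
      stop("d_proj is required when n_neighbors is fixed")
    nt <- neighbor_table(X, max(as.integer(n_neighbors), 1L))
    K <- fixed_neighborhood(nt, n_neighbors)
    est <- NULL
    d_proj <- as.integer(d_proj)
  }
  G <- symmetrize(adaptive_adjacency(nt, K), "union")
  G <- connect_components(G, X)
  emb <- spectral_embed(G, d_proj, row_normalize = row_normalize)
  if (!is.null(seed)) set.seed(seed)
  km <- kmeans(emb$Y, centers = n_clusters, nstart = nstart,
               iter.max = 100L)
  clusters <- structure(list(labels = as.integer(km$cluster),
                             n_clusters = n_clusters,
                             inertia = km$tot.withinss,
                             seed = seed, nstart = nstart),
                        class = "cluster_assignment")
  structure(list(clusters = clusters, embedding = emb, estimate = est,
                 neighborhood = K, graph = G,
                 params = list(tau = tau, alpha = alpha, k_min = k_min,
                               k_max = k_max, d_proj = d_proj,
                               n_neighbors = n_neighbors, seed = seed)),
            class = "sc_star")
}

#' @export
print.sc_star <- function(x, ...) {
  cat("adaptive spectral clustering:", x$clusters$n_clusters,
      "clusters, inertia", format(x$clusters$inertia), "\n")
  if (!is.null(x$estimate)) print(x$estimate)
  invisible(x)
}
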