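#' Fit the low-dimensional similarity curve parameters
#'
#' Least-squares fit of `1 / (1 + a * x^(2b))` to the target kernel that
#' is 1 up to `min_dist` and decays as `exp(-(x - min_dist) / spread)`
#' beyond it.  These are the `a`, `b` constants of the embedding-space
#' similarity used by the cross-entropy layout.
#'
#' @param spread scale of the decay.
#' @param min_dist distance below which points are treated as maximally
#'   similar.
#' @return named numeric vector `c(a, b)`.
#' @export
find_ab_params <- function(spread = 1.0, min_dist = 0.1) {
  xv <- seq(0, spread * 3, length.out = 300L)
  yv <- ifelse(xv < min_dist, 1, exp(-(xv - min_dist) / spread))
  fit <- nls(yv ~ 1 / (1 + a * xv^(2 * b)),
             start = list(a = 1.5, b = 1.0),
             control = list(maxiter = 200L))
  c(a = unname(coef(fit)["a"]), b = unname(coef(fit)["b"]))
}

#' Calibrate per-point fuzzy neighbourhood scales
#'
#' For every point i with adaptive neighbourhood size `k*_i`, finds the
#' local scale `sigma_i` such that the fuzzy memberships of its `k*_i`
#' nearest neighbours sum to `log2(k*_i)`:
#' `sum_j exp(-max(0, d_ij - rho_i) / sigma_i) = log2(k*_i)`,
#' where `rho_i` (the connectivity offset) is the distance to the first
#' non-coincident neighbour, so that neighbour always receives membership
#' exactly 1.  The scale is found by bisection to within `tol` (or
#' `max_iter` halvings) and floored at `floor_factor` times the point's
#' mean neighbour distance.  A point with `k*_i = 1` has unattainable
#' target `log2(1) = 0`; its scale is set to the floor with a warning.
#'
#' @param nt a [neighbor_table()].
#' @param K an `adaptive_neighborhood`.
#' @param tol calibration tolerance on the membership sum.
#' @param max_iter bisection iteration cap.
#' @param floor_factor lower bound on `sigma` relative to the mean
#'   neighbour distance.
#' @return class `fuzzy_calibration`: vectors `conn_offset` (rho),
#'   `sigma`, `target`, `achieved`, and the count `n_floored`.
#' @export
smooth_knn_calibration <- function(nt, K, tol = 1e-5, max_iter = 64L,
                                   floor_factor = 1e-3) {
  stopifnot(inherits(nt, "neighbor_table"),
            inherits(K, "adaptive_neighborhood"))
  n <- nt$n
  ks <- pmin(K$k_star, nt$k_max)
  rho <- numeric(n); sigma <- numeric(n)
  target <- log2(ks); achieved <- numeric(n)
  n_floored <- 0L
  for (i in seq_len(n)) {
    d <- nt$distances[i, seq_len(ks[i]), drop = TRUE]
    pos <- d[d > 0]
    rho[i] <- if (length(pos)) pos[1] else 0
    floor_i <- max(floor_factor * mean(d), .Machine$double.eps)
    if (target[i] <= 0) {            # k* = 1: target log2(1) = 0
      sigma[i] <- floor_i
      n_floored <- n_floored + 1L
      achieved[i] <- sum(exp(-pmax(0, d - rho[i]) / sigma[i]))
      next
    }
    dd <- pmax(0, d - rho[i])
    psum <- function(s) sum(exp(-dd / s))
    lo <- 0; hi <- Inf; mid <- 1
    for (it in seq_len(max_iter)) {
      val <- psum(mid)
      if (abs(val - target[i]) < tol) break
      if (val > target[i]) {         # sum increases with sigma
        hi <- mid
        mid <- (lo + hi) / 2
      } else {
        lo <- mid
        mid <- if (is.finite(hi)) (lo + hi) / 2 else mid * 2
      }
    }
    sigma[i] <- max(mid, floor_i)
    achieved[i] <- psum(sigma[i])
  }
  if (n_floored > 0L)
    warning(n_floored, " point(s) with k* = 1: target log2(1) = 0 is ",
            "unattainable; sigma set to its floor")
  structure(list(conn_offset = rho, sigma = sigma, target = target,
                 achieved = achieved, n_floored = n_floored),
            class = "fuzzy_calibration")
}

#' Fuzzy membership graph on the adaptive adjacency
#'
#' Directed fuzzy weights
#' `w_ij = exp(-max(0, d_ij - rho_i) / sigma_i)` on the adaptive
#' adjacency support, merged into a symmetric graph by the probabilistic
#' t-conorm `W + W' - W * W'` (the fuzzy union).  All weights lie in
#' `(0, 1]` and are non-increasing in neighbour distance for each point.
#'
#' @param nt a [neighbor_table()].
#' @param K an `adaptive_neighborhood`.
#' @param cal a `fuzzy_calibration`; computed from `nt`, `K` if missing.
#' @param symmetrize_graph if `FALSE`, return the directed membership
#'   graph instead of its fuzzy union.
#' @return a `weight_graph` of kind `"fuzzy"`.
#' @export
fuzzy_graph <- function(nt, K, cal = NULL, symmetrize_graph = TRUE) {
  stopifnot(inherits(nt, "neighbor_table"),
            inherits(K, "adaptive_neighborhood"))
  cal <- cal %||% smooth_knn_calibration(nt, K)
  n <- nt$n
  ks <- pmin(K$k_star, nt$k_max)
  ii <- rep.int(seq_len(n), ks)
  jj <- unlist(lapply(seq_len(n),
                      function(i) nt$indices[i, seq_len(ks[i])]),
               use.names = FALSE)
  dd <- unlist(lapply(seq_len(n),
                      function(i) nt$distances[i, seq_len(ks[i])]),
               use.names = FALSE)
  ww <- exp(-pmax(0, dd - cal$conn_offset[ii]) / cal$sigma[ii])
  W <- sparseMatrix(i = ii, j = jj, x = ww, dims = c(n, n))
  G <- weight_graph(W, kind = "fuzzy", symmetrized = FALSE)
  if (symmetrize_graph) symmetrize(G, "fuzzy_union") else G
}

## epochs-per-sample schedule: edges are sampled proportionally to their
## membership weight; edges too weak to be sampled once are dropped
edge_schedule <- function(G, n_epochs) {
  tr <- methods::as(G$W, "TsparseMatrix")
  w <- tr@x
  keep <- w >= max(w) / n_epochs
  list(head = tr@i[keep], tail = tr@j[keep],
       epochs_per_sample = max(w) / w[keep])
}

#' Adaptive fuzzy simplicial (UMAP-style) embedding
#'
#' Full pipeline: adaptive neighbourhood estimation, per-point fuzzy
#' calibration to target `log2(k*_i)`, fuzzy-union graph assembly, and a
#' stochastic cross-entropy layout (attraction along sampled edges,
#' repulsion against negative samples) in `d_proj` dimensions, defaulting
#' to the rounded intrinsic dimension estimate.  The layout is
#' initialised from the spectral embedding of the fuzzy graph and is
#' reproducible given `seed`; the high-dimensional fuzzy graph itself is
#' deterministic.  Passing `n_neighbors` degenerates the graph stage to a
#' fixed-k fuzzy graph.
#'
#' @param X data matrix.
#' @param d_proj target dimension (defaults to the dimension estimate).
#' @param n_neighbors optional fixed neighbourhood size (baseline mode;
#'   requires `d_proj`).
#' @param n_epochs layout epochs.
#' @param min_dist,spread low-dimensional kernel shape; see
#'   [find_ab_params()].
#' @param negative_sample_rate repulsive samples per attractive update.
#' @param learning_rate initial layout step size (decays linearly).
#' @param seed RNG seed for the layout stage.
#' @param tau,alpha,k_min,k_max,tol,max_iter parameters passed to
#'   [abide()].
#' @return class `umap_star`: list with `embedding`, `estimate`,
#'   `neighborhood`, `calibration`, `graph`, `params`.
#' @export
umap_star <- function(X, d_proj = NULL, n_neighbors = NULL,
                      n_epochs = 500L, min_dist = 0.1, spread = 1.0,
                      negative_sample_rate = 5L, learning_rate = 1.0,
                      seed = NULL, tau = 0.5, alpha = 0.01, k_min = 3L,
                      k_max = NULL, tol = 1e-3, max_iter = 50L) {
  X <- check_data_matrix(X)
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
  cal <- smooth_knn_calibration(nt, K)
  G <- fuzzy_graph(nt, K, cal)
  ab <- find_ab_params(spread, min_dist)
  if (!is.null(seed)) set.seed(seed)
  ## spectral initialisation from the fuzzy graph (connected copy)
  Ginit <- connect_components(G, X)
  init <- spectral_embed(Ginit, d_proj)$Y
  init <- apply(init, 2L, function(u) {
    r <- max(abs(u)); if (r == 0) u else 10 * u / r
  })
  init <- init + matrix(rnorm(length(init), sd = 1e-4), nrow(init))
  sched <- edge_schedule(G, n_epochs)
  Y <- matrix(as.numeric(init), n, d_proj)
  optimize_umap_layout(Y, sched$head, sched$tail,
                       sched$epochs_per_sample,
                       as.integer(n_epochs), ab["a"], ab["b"],
                       1.0, learning_rate,
                       as.integer(negative_sample_rate))
  emb <- new_embedding(Y, "umap_star", centered = FALSE,
                       unit_cov = FALSE)
  structure(list(embedding = emb, estimate = est, neighborhood = K,
                 calibration = cal, graph = G,
                 params = list(tau = tau, alpha = alpha, k_min = k_min,
                               k_max = k_max, d_proj = d_proj,
                               n_neighbors = n_neighbors,
                               n_epochs = n_epochs, min_dist = min_dist,
                               spread = spread, a = ab[["a"]],
                               b = ab[["b"]],
                               negative_sample_rate = negative_sample_rate,
                               seed = seed)),
            class = "umap_star")
}

#' @export
print.umap_star <- function(x, ...) {
  cat("adaptive fuzzy-graph embedding\n")
  if (!is.null(x$estimate)) print(x$estimate)
  print(x$embedding)
  invisible(x)
}
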