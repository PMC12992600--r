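#' Local barycentric reconstruction weights
#'
#' Solves the constrained least squares that reconstructs `X[i, ]` from
#' the rows `X[nbrs, ]`, with the weights constrained to sum to one: the
#' local Gram system `G w = 1` is solved and `w` rescaled, where
#' `G = C C'` and `C` holds the neighbours centred at the point.  When the
#' Gram matrix is singular or there are more neighbours than features, a
#' ridge proportional to its trace is added.
#'
#' Ridge policies: `"conditional"` (default) solves the well-posed Gram
#' system exactly; when the Gram matrix is singular but an exact
#' barycentric reconstruction exists (the constrained objective attains
#' zero, e.g. on locally flat data with `k > d`), the minimum-norm
#' zero-residual weights are returned, and only otherwise is a ridge
#' `reg * trace(G) / k` added.  `"always"` adds `reg * trace(G)`
#' unconditionally (the convention of the reference
#' locally-linear-embedding implementations, used by the degeneration
#' checks); `"none"` refuses singular systems.
#'
#' @param X data matrix.
#' @param i index of the point to reconstruct.
#' @param nbrs indices of its neighbours (nonempty, excluding `i`).
#' @param reg ridge coefficient.
#' @param reg_policy one of `"conditional"`, `"always"`, `"none"`.
#' @return weight vector of length `length(nbrs)` summing to 1.
#' @export
#' @examples
#' X <- cbind(c(1, 0, 4))
#' local_weights(X, 1, c(2, 3))  # 0.75, 0.25
local_weights <- function(X, i, nbrs, reg = 1e-3,
                          reg_policy = c("conditional", "always", "none")) {
  reg_policy <- match.arg(reg_policy)
  if (length(nbrs) == 0L) stop("empty neighbourhood")
  if (i %in% nbrs) stop("a point cannot be its own neighbour")
  k <- length(nbrs)
  C <- X[nbrs, , drop = FALSE] -
    matrix(X[i, ], k, ncol(X), byrow = TRUE)
  G <- tcrossprod(C)
  trG <- sum(diag(G))
  if (trG <= 0) return(rep(1 / k, k))   # all neighbours coincide with x_i
  if (reg_policy == "always") {
    G <- G + diag(reg * trG, k)
    w <- solve(G, rep(1, k))
    return(w / sum(w))
  }
  if (rcond(G) > 1e-10) {               # well-posed Gram system
    w <- solve(G, rep(1, k))
    return(w / sum(w))
  }
  if (reg_policy == "none")
    stop("singular local Gram matrix and regularisation disabled")
  ## Singular Gram.  If the neighbourhood is locally degenerate (it
  ## spans a proper affine subspace that contains the point, as on
  ## exactly flat data) or the constrained solution is unique, the
  ## objective attains zero and the minimum-norm zero-residual weights
  ## w = B'(B B')^+ c, B = [C'; 1'], c = (0, ..., 0, 1), are exact.
  ## Otherwise (k > D + 1 on generic data: feasibility is vacuous) the
  ## standard ridge keeps the reconstruction manifold-following.
  B <- rbind(t(C), rep(1, k))
  cvec <- c(rep(0, ncol(C)), 1)
  s <- svd(B, nu = min(nrow(B), k), nv = min(nrow(B), k))
  pos <- s$d > 1e-10 * s$d[1]
  rank_C <- sum(svd(C, nu = 0, nv = 0)$d > 1e-10 * s$d[1])
  unique_sol <- sum(pos) == k
  degenerate_geom <- rank_C < ncol(X)
  if (unique_sol || degenerate_geom) {
    w <- as.numeric(s$v[, pos, drop = FALSE] %*%
      ((crossprod(s$u[, pos, drop = FALSE], cvec)) / s$d[pos]))
    if (max(abs(as.numeric(B %*% w) - cvec)) < 1e-8 * sqrt(trG / k + 1))
      return(w / sum(w))
  }
  ## ridge the singular Gram system
  G <- G + diag(reg * trG / k, k)
  w <- solve(G, rep(1, k))
  w / sum(w)
}

#' Global sparse weight matrix of barycentric reconstructions
#'
#' Fills the support of a directed binary adjacency with the local
#' reconstruction weights of every point on its own neighbours; entries
#' off the support are zero and each nonempty row sums to one.
#'
#' @param X data matrix.
#' @param A a binary, directed `weight_graph` (from
#'   [adaptive_adjacency()]).
#' @inheritParams local_weights
#' @return a `weight_graph` of kind `"lle_weights"`.
#' @export
assemble_weight_matrix <- function(X, A, reg = 1e-3,
                                   reg_policy = "conditional") {
  stopifnot(inherits(A, "weight_graph"))
  if (A$kind != "binary") stop("adjacency must be binary")
  X <- check_data_matrix(X)
  tr <- methods::as(A$W, "TsparseMatrix")
  nbr_list <- split(tr@j + 1L, tr@i + 1L)
  n <- A$n
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  ii <- rep.int(as.integer(names(nbr_list)),
                lengths(nbr_list))
  jj <- unlist(nbr_list, use.names = FALSE)
  xx <- unlist(lapply(names(nbr_list), function(nm) {
    i <- as.integer(nm)
    local_weights(X, i, nbr_list[[nm]], reg = reg, reg_policy = reg_policy)
  }), use.names = FALSE)
  W <- sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  weight_graph(W, kind = "lle_weights", symmetrized = FALSE)
}

new_embedding <- function(Y, method, ...) {
  structure(c(list(Y = Y, d_proj = ncol(Y), method = method), list(...)),
            class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat("embedding:", nrow(x$Y), "x", x$d_proj, "(", x$method, ")\n")
  invisible(x)
}

#' Locally linear embedding from a reconstruction-weight graph
#'
#' Minimises the embedding cost `sum_i || y_i - sum_j W_ij y_j ||^2`
#' subject to centred coordinates with identity sample covariance:
#' the bottom eigenvectors of `M = (I - W)'(I - W)` after discarding the
#' constant one (eigenvalue ~ 0), scaled by `sqrt(n)` so that
#' `(1/n) Y'Y = I` holds literally.  The reported `cost` equals n times
#' the sum of the retained eigenvalues.
#'
#' If the graph's undirected support is disconnected, only the largest
#' connected component is embedded; the remaining rows of `Y` are `NA`
#' and a warning is emitted.
#'
#' @param W a row-stochastic `weight_graph` of kind `"lle_weights"`.
#' @param d_proj embedding dimension, at most `n - 2`.
#' @return an `embedding` with fields `Y`, `cost`, `eigenvalues`,
#'   `centered`, `unit_cov`, and `component` (logical, embedded rows).
#' @export
lle_embed <- function(W, d_proj) {
  stopifnot(inherits(W, "weight_graph"))
  if (W$kind != "lle_weights") stop("expected a reconstruction-weight graph")
  n <- W$n
  d_proj <- as.integer(d_proj)
  if (d_proj < 1L || d_proj > n - 2L) stop("d_proj must be in [1, n - 2]")
  keep <- rep(TRUE, n)
  ig <- igraph::graph_from_adjacency_matrix(
    (W$W != 0) | (Matrix::t(W$W) != 0), mode = "undirected")
  comp <- igraph::components(ig)
  if (comp$no > 1L) {
    warning("adaptive graph is disconnected; embedding the largest ",
            "component (", max(comp$csize), " of ", n, " points)")
    keep <- comp$membership == which.max(comp$csize)
  }
  Wk <- W$W[keep, keep, drop = FALSE]
  ## renormalise rows clipped by the component restriction
  rs <- Matrix::rowSums(Wk)
  if (any(rs == 0)) stop("points with no surviving neighbours; ",
                         "densify the graph")
  Wk <- Diagonal(x = 1 / rs) %*% Wk
  nk <- sum(keep)
  IW <- Diagonal(nk) - Wk
  M <- Matrix::crossprod(IW)
  eig <- tryCatch(bottom_eigs(M, d_proj + 1L),
                  error = function(e)
                    stop("eigen-solver failure (", conditionMessage(e),
                         "); consider densifying the graph"))
  vals <- eig$values
  vecs <- eig$vectors
  ## identify and discard the constant eigenvector
  const <- which(abs(vals) < 1e-8 &
                   apply(vecs, 2L, function(u) sd(u) < 1e-6 * max(abs(u))))
  drop_idx <- if (length(const)) const[1] else 1L
  sel <- setdiff(seq_len(d_proj + 1L), drop_idx)[seq_len(d_proj)]
  U <- vecs[, sel, drop = FALSE]
  ## enforce the printed constraints exactly: project out the constant
  ## direction, then re-orthonormalise the columns
  U <- sweep(U, 2L, colMeans(U))
  U <- U %*% backsolve(chol(crossprod(U)), diag(d_proj))
  Y <- matrix(NA_real_, n, d_proj)
  Y[keep, ] <- sqrt(nk) * U
  new_embedding(Y, "lle_star",
                cost = nk * sum(vals[sel]), eigenvalues = vals[sel],
                centered = TRUE, unit_cov = TRUE, component = keep)
}

#' Adaptive locally linear embedding
#'
#' Full pipeline: estimate the intrinsic dimension and per-point
#' neighbourhood sizes, build the adaptive adjacency, solve the local
#' barycentric weights, and embed in `d_proj` dimensions (defaulting to
#' the rounded dimension estimate; override e.g. `d_proj = 2` for
#' visualisation).  Passing `n_neighbors` forces a fixed neighbourhood
#' size for every point and skips the adaptive estimation — the classical
#' method used as a baseline — in which case `d_proj` must be given.
#'
#' @param X data matrix (n x D).
#' @param d_proj target dimension; default: the rounded dimension
#'   estimate.
#' @param n_neighbors optional fixed neighbourhood size (degeneration to
#'   classical locally linear embedding).
#' @param tau,alpha,k_min,k_max,tol,max_iter parameters passed to
#'   [abide()].
#' @param reg,reg_policy local ridge; see [local_weights()].
#' @return class `lle_star`: list with `embedding`, `estimate` (`NULL`
#'   for fixed-k runs), `neighborhood`, `adjacency`, `weights`,
#'   `neighbors`, the training data `X`, and `params`.
#' @export
lle_star <- function(X, d_proj = NULL, n_neighbors = NULL, tau = 0.5,
                     alpha = 0.01, k_min = 3L, k_max = NULL, tol = 1e-3,
                     max_iter = 50L, reg = 1e-3,
                     reg_policy = "conditional") {
  X <- check_data_matrix(X)
  n <- nrow(X)
  k_max <- as.integer(k_max %||% min(n - 1L, 100L))
  if (is.null(n_neighbors)) {
    fit <- abide(X, tau = tau, alpha = alpha, k_min = k_min,
                 k_max = k_max, tol = tol, max_iter = max_iter)
    nt <- fit$neighbors
    K <- fit$neighborhood
    est <- fit$estimate
    d_proj <- as.integer(d_proj %||% est$d_star)
  } else {
    if (is.null(d_proj))
      stop("d_proj is required when n_neighbors is fixed")
    nt <- neighbor_table(X, max(as.integer(n_neighbors), k_max))
    K <- fixed_neighborhood(nt, n_neighbors)
    est <- NULL
    d_proj <- as.integer(d_proj)
  }
  A <- adaptive_adjacency(nt, K)
  W <- assemble_weight_matrix(X, A, reg = reg, reg_policy = reg_policy)
  emb <- lle_embed(W, d_proj)
  structure(list(embedding = emb, estimate = est, neighborhood = K,
                 adjacency = A, weights = W, neighbors = nt, X = X,
                 params = list(tau = tau, alpha = alpha, k_min = k_min,
                               k_max = k_max, tol = tol,
                               max_iter = max_iter, reg = reg,
                               reg_policy = reg_policy,
                               d_proj = d_proj,
                               n_neighbors = n_neighbors)),
            class = "lle_star")
}

#' @export
print.lle_star <- function(x, ...) {
  cat("adaptive LLE fit\n")
  if (!is.null(x$estimate)) print(x$estimate)
  print(x$embedding)
  invisible(x)
}

#' Out-of-sample projection for an adaptive embedding
#'
#' Projects unseen points into a fitted embedding without refitting.  For
#' each test point: (1) distances to all training points are ranked;
#' (2) its adaptive neighbourhood size is found by the same
#' likelihood-ratio scan used in training, at the trained dimension (the
#' point temporarily augments the training set but is never added to the
#' training graph); (3) barycentric weights on those neighbours are
#' solved; (4) its embedding is the weighted combination of the
#' neighbours' training embeddings.
#'
#' @param object a fitted [lle_star()] model.
#' @param newdata matrix of test points (rows) with the training feature
#'   dimension.
#' @param ... unused.
#' @return matrix of projected coordinates
#'   (`nrow(newdata)` x `d_proj`).
#' @export
predict.lle_star <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$X))
    stop("test dimension mismatch: expected ", ncol(object$X),
         " features")
  nt <- object$neighbors
  p <- object$params
  d_scan <- if (!is.null(object$estimate)) object$estimate$d_hat
            else p$d_proj
  sv <- shell_volumes(nt, d_scan)
  om <- unit_ball_volume(d_scan)
  k_max <- min(p$k_max, nt$k_max)
  k_min <- if (!is.null(p$n_neighbors)) p$n_neighbors else p$k_min
  thr <- if (!is.null(object$neighborhood$D_thr) &&
             is.finite(object$neighborhood$D_thr))
    object$neighborhood$D_thr else qchisq(1 - p$alpha, 1)
  Y <- object$embedding$Y
  out <- matrix(NA_real_, nrow(newdata), ncol(Y))
  for (t in seq_len(nrow(newdata))) {
    q <- query_distances(object$X, newdata[t, ])
    if (!is.null(p$n_neighbors)) {
      k_star <- p$n_neighbors
    } else {
      rd <- q$distances[seq_len(k_max)]^d_scan
      v <- om * c(rd[1], diff(rd))
      V <- cumsum(v)
      k_star <- k_max
      for (k in k_min:(k_max - 1L)) {
        Vj <- sv$V[q$indices[k + 1L], k]
        if (V[k] > 0 && Vj > 0) {
          Dk <- 2 * k * log((V[k] + Vj)^2 / (4 * V[k] * Vj))
          if (Dk >= thr) { k_star <- k; break }
        }
      }
    }
    nbrs <- q$indices[seq_len(k_star)]
    Xa <- rbind(newdata[t, ], object$X)
    w <- local_weights(Xa, 1L, nbrs + 1L, reg = p$reg,
                       reg_policy = p$reg_policy)
    yn <- Y[nbrs, , drop = FALSE]
    if (anyNA(yn)) {
      warning("test point ", t, " has unembedded neighbours; returning NA")
      next
    }
    out[t, ] <- as.numeric(crossprod(yn, w))
  }
  out
}
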