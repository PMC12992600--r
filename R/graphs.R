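## Sparse neighbourhood graphs shared by all embedders.  A weight_graph is
## a thin wrapper around a Matrix::dgCMatrix with a kind tag so downstream
## code can assert what it is consuming.

weight_graph <- function(W, kind = c("binary", "lle_weights", "fuzzy"),
                         symmetrized = FALSE) {
  kind <- match.arg(kind)
  W <- methods::as(methods::as(W, "CsparseMatrix"), "generalMatrix")
  if (any(Matrix::diag(W) != 0)) stop("self-edges are not allowed")
  structure(list(W = W, n = nrow(W), kind = kind,
                 symmetrized = symmetrized),
            class = "weight_graph")
}

#' @export
print.weight_graph <- function(x, ...) {
  cat("weight_graph:", x$n, "vertices,", length(x$W@x), "edges, kind =",
      x$kind, if (x$symmetrized) "(symmetric)" else "(directed)", "\n")
  invisible(x)
}

#' Adaptive binary adjacency matrix
#'
#' Directed k-nearest-neighbour graph in which row i has an edge to each
#' of the `k_star[i]` nearest neighbours of point i.  Row i of the result
#' therefore has exactly `k_star[i]` ones and the diagonal is empty.  When
#' all `k_star` are equal this reduces to the standard kNN graph.
#'
#' @param nt a [neighbor_table()].
#' @param K an `adaptive_neighborhood`.
#' @return a `weight_graph` of kind `"binary"`.
#' @export
adaptive_adjacency <- function(nt, K) {
  stopifnot(inherits(nt, "neighbor_table"),
            inherits(K, "adaptive_neighborhood"))
  ks <- pmin(K$k_star, nt$k_max)
  if (any(ks < 1L)) stop("k_star must be >= 1")
  ii <- rep.int(seq_len(nt$n), ks)
  jj <- unlist(lapply(seq_len(nt$n),
                      function(i) nt$indices[i, seq_len(ks[i])]),
               use.names = FALSE)
  W <- sparseMatrix(i = ii, j = jj, x = 1, dims = c(nt$n, nt$n))
  weight_graph(W, kind = "binary", symmetrized = FALSE)
}

#' Symmetrize a neighbourhood graph
#'
#' Policies: `"union"` takes the elementwise maximum of the graph and its
#' transpose (for binary graphs, the union of edge sets); `"intersection"`
#' keeps mutual edges only (averaging their two weights);
#' `"mean"` is `(W + t(W)) / 2`; `"fuzzy_union"` is the probabilistic
#' t-conorm `W + t(W) - W * t(W)` used to merge directed fuzzy membership
#' weights, and requires weights in `[0, 1]`.
#'
#' @param G a `weight_graph`.
#' @param policy one of `"union"`, `"intersection"`, `"mean"`,
#'   `"fuzzy_union"`.
#' @return a symmetric `weight_graph` of the same kind.
#' @export
symmetrize <- function(G, policy = c("union", "intersection", "mean",
                                     "fuzzy_union")) {
  policy <- match.arg(policy)
  stopifnot(inherits(G, "weight_graph"))
  W <- G$W
  Wt <- Matrix::t(W)
  S <- switch(policy,
    union = {
      gt <- Wt > W                      # support within union, w >= 0
      W + (Wt - W) * gt
    },
    intersection = {
      P <- (W > 0) * (Wt > 0)
      P * (W + Wt) / 2
    },
    mean = (W + Wt) / 2,
    fuzzy_union = {
      if (any(W@x < 0) || any(W@x > 1))
        stop("fuzzy_union requires weights in [0, 1]")
      W + Wt - W * Wt
    })
  S <- Matrix::drop0(S)
  weight_graph(S, kind = G$kind, symmetrized = TRUE)
}

#' Write a graph as a 3-column edge list
#'
#' Tab-delimited `(i, j, w)` triples with 0-based vertex indices.
#'
#' @param G a `weight_graph`.
#' @param path output file.
#' @export
write_edge_list <- function(G, path) {
  stopifnot(inherits(G, "weight_graph"))
  tr <- methods::as(G$W, "TsparseMatrix")
  df <- data.frame(i = tr@i, j = tr@j, w = tr@x)
  df <- df[order(df$i, df$j), ]
  write.table(df, path, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Read a 3-column edge list written by [write_edge_list()]
#'
#' @param path input file with 0-based `(i, j, w)` rows.
#' @param n number of vertices.
#' @param kind edge kind tag.
#' @param symmetrized whether the stored graph was symmetric.
#' @export
read_edge_list <- function(path, n, kind = "binary", symmetrized = FALSE) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("i", "j", "w"))
  W <- sparseMatrix(i = df$i + 1L, j = df$j + 1L, x = df$w, dims = c(n, n))
  weight_graph(W, kind = kind, symmetrized = symmetrized)
}

## Connect a disconnected symmetric graph by repeatedly adding the single
## shortest edge between the smallest component and the rest (computed
## from the ambient coordinates X).  Used before spectral embedding, where
## a disconnected graph would mix component indicator vectors.
connect_components <- function(G, X) {
  stopifnot(inherits(G, "weight_graph"), G$symmetrized)
  repeat {
    ig <- igraph::graph_from_adjacency_matrix(G$W > 0, mode = "undirected")
    comp <- igraph::components(ig)
    if (comp$no == 1L) return(G)
    small <- which(comp$membership == which.min(comp$csize))
    rest <- which(comp$membership != which.min(comp$csize))
    D2 <- outer(rowSums(X[small, , drop = FALSE]^2),
                rowSums(X[rest, , drop = FALSE]^2), "+") -
      2 * tcrossprod(X[small, , drop = FALSE], X[rest, , drop = FALSE])
    hit <- arrayInd(which.min(D2), dim(D2))
    i <- small[hit[1]]; j <- rest[hit[2]]
    message("connecting components: adding edge ", i, " -- ", j)
    W <- G$W
    W[i, j] <- W[j, i] <- max(W@x)
    G <- weight_graph(Matrix::drop0(W), kind = G$kind, symmetrized = TRUE)
  }
}
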