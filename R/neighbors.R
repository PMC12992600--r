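#' Read a delimited numeric matrix
#'
#' Reads observations-by-features data from comma- or tab-delimited text.
#' The delimiter is sniffed from the first line unless given; an optional
#' header row is detected by attempting numeric conversion.  The file must
#' be strictly rectangular and all entries finite.
#'
#' @param path path to a delimited text file, rows = observations.
#' @param sep field separator; `"auto"` (default) tries tab, then comma.
#' @param header `TRUE`, `FALSE` or `"auto"`.
#' @return a numeric matrix.
#' @export
read_matrix <- function(path, sep = "auto", header = "auto") {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (identical(sep, "auto")) sep <- if (grepl("\t", first)) "\t" else ","
  if (identical(header, "auto")) {
    fields <- strsplit(first, sep, fixed = TRUE)[[1]]
    header <- any(is.na(suppressWarnings(as.numeric(fields))))
  }
  df <- read.table(path, sep = sep, header = header, fill = FALSE,
                   strip.white = TRUE, check.names = FALSE)
  X <- as.matrix(df)
  if (!is.numeric(X)) stop("non-numeric entries in ", path)
  if (any(!is.finite(X))) stop("non-finite entries in ", path)
  dimnames(X) <- NULL
  X
}

check_data_matrix <- function(X) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("data matrix must be numeric")
  if (nrow(X) < 2L) stop("need at least 2 observations")
  if (any(!is.finite(X))) stop("data matrix contains non-finite entries")
  storage.mode(X) <- "double"
  X
}

#' Exact sorted nearest-neighbour table
#'
#' Computes, for every point, the indices and Euclidean distances of its
#' `k_max` nearest neighbours (the point itself is never counted among its
#' own neighbours).  Neighbours are exact and sorted by distance, with ties
#' broken by ascending point index so all downstream graph structures are
#' reproducible.  Coincident points are retained: a duplicated row appears
#' as a neighbour at distance zero.
#'
#' @param X numeric matrix, n observations x D features.
#' @param k_max number of neighbours to record, `1 <= k_max <= n - 1`.
#' @param block row-block size used when forming pairwise distances, a
#'   memory/speed trade-off with no effect on the result.
#' @return an object of class `neighbor_table`: a list with integer matrix
#'   `indices` (n x k_max), numeric matrix `distances` (n x k_max,
#'   non-decreasing along each row), `k_max` and `n`.
#' @export
#' @examples
#' nt <- neighbor_table(cbind(c(0, 1, 3)), k_max = 2)
#' nt$distances[1, ]  # 1 3
neighbor_table <- function(X, k_max, block = 2048L) {
  X <- check_data_matrix(X)
  n <- nrow(X)
  k_max <- as.integer(k_max)
  if (k_max < 1L || k_max >= n)
    stop("insufficient points: need 1 <= k_max <= n - 1")
  sq <- rowSums(X^2)
  indices <- matrix(0L, n, k_max)
  distances <- matrix(0, n, k_max)
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    D2 <- outer(sq[rows], sq, "+") - 2 * tcrossprod(X[rows, , drop = FALSE], X)
    D2[D2 < 0] <- 0
    for (r in seq_along(rows)) {
      i <- rows[r]
      d <- sqrt(D2[r, ])
      d[i] <- Inf                       # exclude self
      ord <- order(d, seq_len(n))[seq_len(k_max)]  # ties -> lower index
      indices[i, ] <- ord
      distances[i, ] <- d[ord]
    }
  }
  structure(list(indices = indices, distances = distances,
                 k_max = k_max, n = n),
            class = "neighbor_table")
}

#' @export
print.neighbor_table <- function(x, ...) {
  cat("neighbor_table:", x$n, "points, k_max =", x$k_max, "\n")
  invisible(x)
}

## distances from a single query point to all rows of X, sorted with the
## same tie-break as neighbor_table(); used by the out-of-sample rule
query_distances <- function(X, x_query) {
  if (length(x_query) != ncol(X))
    stop("query dimension mismatch: expected ", ncol(X), " features")
  d <- sqrt(pmax(rowSums(sweep(X, 2L, x_query)^2), 0))
  ord <- order(d, seq_along(d))
  list(indices = ord, distances = d[ord])
}
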