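## Bottom eigenpairs of a symmetric positive semi-definite sparse matrix.
## Dense LAPACK for small problems; otherwise shift-invert ARPACK (via
## igraph) with a sparse Cholesky factor of M + eps*I, so the smallest
## eigenvalues of M become the well-separated largest eigenvalues of the
## inverse.  Eigenvalues are recovered from Rayleigh quotients of the
## converged vectors.
bottom_eigs <- function(M, nev, dense_cutoff = 1500L) {
  n <- nrow(M)
  nev <- min(nev, n)
  if (n <= dense_cutoff) {
    e <- eigen(as.matrix(M), symmetric = TRUE)
    ord <- order(e$values)
    return(list(values = e$values[ord][seq_len(nev)],
                vectors = e$vectors[, ord[seq_len(nev)], drop = FALSE]))
  }
  Msym <- Matrix::forceSymmetric(M)
  eps <- 1e-8 * mean(Matrix::diag(Msym))
  ch <- tryCatch(Matrix::Cholesky(Msym + eps * Diagonal(n),
                                  LDL = FALSE, perm = TRUE),
                 error = function(e) NULL)
  opts <- list(n = n, nev = nev,
               ncv = min(n, max(4L * nev + 10L, 30L)),
               which = "LA", maxiter = 10000L)
  if (!is.null(ch)) {
    fn <- function(x, extra = NULL)
      as.numeric(Matrix::solve(ch, x, system = "A"))
    r <- igraph::arpack(fn, sym = TRUE, options = opts)
    vecs <- r$vectors
    if (is.null(dim(vecs))) vecs <- matrix(vecs, ncol = 1L)
    ## Rayleigh quotients of M on the converged invariant subspace
    vals <- colSums(vecs * as.matrix(Msym %*% vecs))
  } else {
    ## fallback: power-shifted operator s*I - M (s >= lambda_max)
    v <- rep(1 / sqrt(n), n) + sin(seq_len(n))
    v <- v / sqrt(sum(v^2))
    lam <- 0
    for (i in 1:60) {
      w <- as.numeric(Msym %*% v)
      lam <- sqrt(sum(w^2))
      if (lam == 0) break
      v <- w / lam
    }
    s <- lam * 1.05 + 1e-8
    fn <- function(x, extra = NULL) s * x - as.numeric(Msym %*% x)
    r <- igraph::arpack(fn, sym = TRUE, options = opts)
    vecs <- r$vectors
    if (is.null(dim(vecs))) vecs <- matrix(vecs, ncol = 1L)
    vals <- s - r$values
  }
  ord <- order(vals)
  list(values = vals[ord][seq_len(nev)],
       vectors = vecs[, ord[seq_len(nev)], drop = FALSE])
}
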