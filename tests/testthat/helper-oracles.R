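## shared fixtures and small independent oracles used across the suite

## relative error after optimal orthogonal alignment (and optional
## isotropic rescaling) of Y onto Z -- embeddings are defined up to
## rotation/reflection, so comparisons go through this
procrustes_error <- function(Y, Z, scale = TRUE) {
  Y <- scale(Y, center = TRUE, scale = FALSE)
  Z <- scale(Z, center = TRUE, scale = FALSE)
  s <- svd(crossprod(Z, Y))
  R <- s$v %*% t(s$u)
  Yr <- Y %*% R
  if (scale) {
    c_opt <- sum(Yr * Z) / sum(Yr^2)
    Yr <- c_opt * Yr
  }
  sqrt(sum((Yr - Z)^2) / sum(Z^2))
}

random_rotation <- function(p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  qr_dec <- qr(matrix(rnorm(p * p), p))
  Q <- qr.Q(qr_dec)
  Q %*% diag(sign(diag(qr.R(qr_dec))), p)
}

## points on a 2-D affine plane embedded in D dims, plus the latent coords
make_plane <- function(n, D = 5, seed = 1, sd_latent = 1) {
  set.seed(seed)
  latent <- matrix(rnorm(n * 2, sd = sd_latent), n, 2)
  B <- qr.Q(qr(matrix(rnorm(D * 2), D, 2)))
  shift <- rnorm(D)
  list(X = latent %*% t(B) + matrix(shift, n, D, byrow = TRUE),
       latent = latent)
}

make_blobs <- function(n_per = 60, sep = 20, D = 4, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * D), n_per, D),
             matrix(rnorm(n_per * D, mean = sep), n_per, D))
  list(X = X, labels = rep(1:2, each = n_per))
}

## run a python snippet; returns stdout lines (python + numpy/sklearn/umap
## serve as independent reference implementations on tiny fixtures)
run_python <- function(code) {
  f <- tempfile(fileext = ".py")
  writeLines(code, f)
  out <- suppressWarnings(system2("python", f, stdout = TRUE,
                                  stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("python oracle failed:\n", paste(out, collapse = "\n"))
  out
}

## enumerate all set partitions of 1..n (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  recurse <- function(labels, k) {
    if (length(labels) == n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (g in seq_len(k + 1L)) recurse(c(labels, g), max(k, g))
  }
  recurse(integer(0), 0L)
  out
}

## pair-counting clustering indices from first principles: iterate over
## all unordered point pairs and tally co-membership agreement
pair_counting_ari <- function(truth, pred) {
  n <- length(truth)
  a <- b <- c_ <- d <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    st <- truth[i] == truth[j]
    sp <- pred[i] == pred[j]
    if (st && sp) a <- a + 1
    else if (st && !sp) b <- b + 1
    else if (!st && sp) c_ <- c_ + 1
    else d <- d + 1
  }
  tot <- a + b + c_ + d
  exp_a <- (a + b) * (a + c_) / tot
  max_a <- ((a + b) + (a + c_)) / 2
  if (max_a == exp_a) return(if (a == exp_a) 1 else 0)
  (a - exp_a) / (max_a - exp_a)
}

## entropy-based indices computed directly from label frequencies
entropy_metrics_oracle <- function(truth, pred) {
  n <- length(truth)
  H <- function(x) {
    p <- table(x) / length(x)
    -sum(p * log(p))
  }
  Hcond <- function(a, b) {  # H(a | b)
    tot <- 0
    for (lev in unique(b)) {
      sel <- b == lev
      tot <- tot + sum(sel) / n * H(a[sel])
    }
    tot
  }
  h <- if (H(truth) == 0) 1 else 1 - Hcond(truth, pred) / H(truth)
  c_ <- if (H(pred) == 0) 1 else 1 - Hcond(pred, truth) / H(pred)
  v <- if (h + c_ == 0) 0 else 2 * h * c_ / (h + c_)
  list(homogeneity = h, completeness = c_, v_measure = v)
}
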