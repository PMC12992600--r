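#' Volume of the unit d-dimensional ball
#'
#' `pi^(d/2) / gamma(d/2 + 1)` for real `d > 0`.  Real-valued dimensions
#' are allowed because the iterative estimator evaluates shell volumes at
#' non-integer candidate dimensions.
#'
#' @param d dimension, real, positive.
#' @return the volume of the unit ball in `d` dimensions.
#' @export
#' @examples
#' unit_ball_volume(1)  # 2
#' unit_ball_volume(2)  # pi
unit_ball_volume <- function(d) {
  if (any(!is.finite(d)) || any(d <= 0)) stop("d must be positive")
  pi^(d / 2) / gamma(d / 2 + 1)
}

#' Hyper-spherical shell volumes of a neighbour table
#'
#' For every point i and neighbour order j, the Lebesgue volume of the
#' d-dimensional shell between the (j-1)-th and j-th neighbour radii,
#' `v[i, j] = Omega_d * (r[i, j]^d - r[i, j-1]^d)` with `r[i, 0] = 0`,
#' where `Omega_d` is the unit-ball volume.  Under local homogeneity of the
#' sampling point process at intensity `rho_i`, the shell volumes of point
#' i are i.i.d. exponential with rate `rho_i`, which is what the
#' likelihood-ratio scan exploits.  Duplicated points yield zero-volume
#' shells, which are retained here; consumers skip scan positions whose
#' cumulative volume is still zero.
#'
#' @param nt a [neighbor_table()].
#' @param d dimension at which to evaluate volumes (real, positive).
#' @return class `shell_volumes`: list with matrices `v` (per-shell) and
#'   `V` (cumulative along each row) plus `d_used`.
#' @export
shell_volumes <- function(nt, d) {
  stopifnot(inherits(nt, "neighbor_table"))
  if (!is.finite(d) || d <= 0) stop("d must be positive")
  om <- unit_ball_volume(d)
  rd <- nt$distances^d
  v <- om * cbind(rd[, 1L], rd[, -1L, drop = FALSE] -
                    rd[, -nt$k_max, drop = FALSE])
  v[v < 0] <- 0   # guard fp noise on ties
  V <- v
  if (nt$k_max > 1L) V <- t(apply(v, 1L, cumsum))
  structure(list(v = v, V = V, d_used = d), class = "shell_volumes")
}

#' Likelihood-ratio statistic for equality of two local intensities
#'
#' Tests whether the homogeneous Poisson intensity around a point equals
#' the intensity around its (k+1)-th nearest neighbour, using the
#' exponential likelihood of k shell volumes on each side.  With the
#' profile maximum-likelihood intensities `k/V` (separate) and
#' `2k/(V_i + V_j)` (common), the deviance has the closed form
#' `D = 2 k log((V_i + V_j)^2 / (4 V_i V_j))`, which is nonnegative and
#' zero iff `V_i = V_j`, and is asymptotically chi-squared with 1 degree
#' of freedom under equality.
#'
#' @param V_i cumulative volume of the first k shells of the point.
#' @param V_j cumulative volume of the first k shells of its (k+1)-th
#'   nearest neighbour.
#' @param k number of shells entering each likelihood.
#' @return the deviance statistic (vectorised over its arguments).
#' @export
#' @examples
#' lrt_statistic(1, 1, 5)   # 0
#' lrt_statistic(1, 3, 5)   # 10 * log(4/3)
lrt_statistic <- function(V_i, V_j, k) {
  if (any(V_i <= 0) || any(V_j <= 0))
    stop("degenerate shells: cumulative volumes must be positive")
  if (any(k < 1)) stop("k must be >= 1")
  2 * k * log((V_i + V_j)^2 / (4 * V_i * V_j))
}

#' Per-point adaptive neighbourhood sizes
#'
#' Scans k = `k_min`, ..., `k_max - 1` and selects, for every point, the
#' smallest k at which the likelihood-ratio statistic comparing the
#' point's local intensity with that of its (k+1)-th nearest neighbour
#' meets or exceeds the `(1 - alpha)` quantile of the chi-squared
#' distribution with 1 df.  Points whose scan never triggers are capped at
#' `k_max`.  Smaller `alpha` values therefore yield larger uniform
#' neighbourhoods.  Scan positions where either cumulative shell volume is
#' still zero (runs of duplicated points) are skipped.
#'
#' @param nt a [neighbor_table()].
#' @param d dimension at which shell volumes are evaluated.
#' @param alpha test level in (0, 1).
#' @param k_min first neighbour order tested (very small k make the test
#'   noisy).
#' @param k_max scan cap; defaults to the table width.
#' @param keep_statistics keep the full n x (k_max - 1) deviance matrix as
#'   diagnostics.
#' @return class `adaptive_neighborhood`: list with integer vector
#'   `k_star`, logical `capped`, `alpha`, `D_thr` (the chi-squared
#'   threshold), `k_min`, `k_max`, and optionally `statistics`.
#' @export
select_kstar <- function(nt, d, alpha = 0.01, k_min = 3L,
                         k_max = nt$k_max, keep_statistics = FALSE) {
  stopifnot(inherits(nt, "neighbor_table"))
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  k_max <- min(as.integer(k_max), nt$k_max)
  k_min <- max(1L, as.integer(k_min))
  if (k_min >= k_max) stop("k_min must be < k_max")
  sv <- shell_volumes(nt, d)
  V <- sv$V
  n <- nt$n
  thr <- qchisq(1 - alpha, df = 1)
  k_star <- rep(k_max, n)
  capped <- rep(TRUE, n)
  stat <- if (keep_statistics) matrix(NA_real_, n, k_max - 1L) else NULL
  for (k in k_min:(k_max - 1L)) {
    j <- nt$indices[, k + 1L]
    Vi <- V[, k]
    Vj <- V[cbind(j, k)]
    ok <- Vi > 0 & Vj > 0
    Dk <- rep(NA_real_, n)
    Dk[ok] <- 2 * k * log((Vi[ok] + Vj[ok])^2 / (4 * Vi[ok] * Vj[ok]))
    if (keep_statistics) stat[, k] <- Dk
    hit <- capped & !is.na(Dk) & Dk >= thr
    k_star[hit] <- k
    capped[hit] <- FALSE
  }
  structure(list(k_star = as.integer(k_star), capped = capped,
                 alpha = alpha, D_thr = thr, k_min = k_min, k_max = k_max,
                 statistics = stat),
            class = "adaptive_neighborhood")
}

#' Fixed (non-adaptive) neighbourhood structure
#'
#' Builds an `adaptive_neighborhood` whose sizes are all equal to `k`.
#' This is the degeneration path used by the non-adaptive baselines
#' (classical LLE, fixed-k spectral clustering, fixed-k fuzzy graphs) and
#' by the grid-search harness.
#'
#' @param n number of points (or a [neighbor_table()]).
#' @param k the common neighbourhood size.
#' @export
fixed_neighborhood <- function(n, k) {
  if (inherits(n, "neighbor_table")) {
    if (k > n$k_max) stop("k exceeds table width")
    n <- n$n
  }
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  structure(list(k_star = rep(k, n), capped = rep(FALSE, n),
                 alpha = NA_real_, D_thr = NA_real_,
                 k_min = k, k_max = k, statistics = NULL, fixed = TRUE),
            class = "adaptive_neighborhood")
}

#' @export
print.adaptive_neighborhood <- function(x, ...) {
  cat("adaptive_neighborhood: n =", length(x$k_star),
      " median k* =", stats::median(x$k_star),
      " capped:", sum(x$capped), "\n")
  invisible(x)
}

#' Concentric-ball counts induced by the adaptive neighbourhoods
#'
#' For each point, the outer radius is the distance to its k*-th
#' neighbour (`k_B = k*`), the inner radius is `tau` times that, and
#' `k_A` counts neighbours within the inner radius (boundary included).
#' Points whose outer radius is zero (all recorded neighbours coincident)
#' cannot define concentric balls and are excluded from the sums with a
#' warning.
#'
#' @param nt a [neighbor_table()].
#' @param K an `adaptive_neighborhood` (from [select_kstar()] or
#'   [fixed_neighborhood()]).
#' @param tau radius ratio in (0, 1).
#' @return class `binomial_counts`: integer vectors `kA`, `kB`, the `tau`
#'   used, and logical `excluded` flagging dropped points.
#' @export
counts_from_kstar <- function(nt, K, tau) {
  stopifnot(inherits(nt, "neighbor_table"),
            inherits(K, "adaptive_neighborhood"))
  if (tau <= 0 || tau >= 1) stop("tau must be in (0, 1)")
  n <- nt$n
  ks <- pmin(K$k_star, nt$k_max)
  rB <- nt$distances[cbind(seq_len(n), ks)]
  excluded <- rB <= 0
  if (any(excluded))
    warning(sum(excluded), " point(s) with zero outer radius excluded ",
            "from the binomial counts")
  ## boundary counted by <=, with a relative guard so tau -> 1 recovers
  ## kA = kB despite rounding of tau * rB
  rA <- tau * rB * (1 + 1e-9)
  kA <- integer(n)
  for (i in seq_len(n))
    kA[i] <- sum(nt$distances[i, seq_len(ks[i])] <= rA[i])
  structure(list(kA = kA[!excluded], kB = ks[!excluded], tau = tau,
                 excluded = excluded),
            class = "binomial_counts")
}

#' Binomial intrinsic-dimension estimate
#'
#' Closed-form maximiser of the binomial likelihood of the intrinsic
#' dimension given counts in concentric balls with radius ratio `tau`:
#' `d_hat = log(sum(kA) / sum(kB)) / log(tau)`.  Conditional on the outer
#' count, the inner count is Binomial with success probability
#' approximately `tau^d` when the sampling process is locally homogeneous.
#'
#' @param counts a `binomial_counts` object (or a list with `kA`, `kB`,
#'   `tau`).
#' @return the point estimate of the intrinsic dimension.
#' @export
#' @examples
#' bide_estimate(list(kA = 25, kB = 100, tau = 0.5))  # 2
bide_estimate <- function(counts) {
  sA <- sum(counts$kA)
  sB <- sum(counts$kB)
  if (sB <= 0) stop("no outer-ball counts")
  if (sA > sB) stop("inner counts exceed outer counts")
  if (sA == 0) stop("empty inner balls (increase tau)")
  log(sA / sB) / log(counts$tau)
}

#' Approximate standard deviation of the dimension estimate
#'
#' Delta-method value `sqrt((1 - p) / (p * sum(kB) * log(tau)^2))` with
#' `p = tau^d_hat`, treating the pooled inner count as Binomial with
#' `sum(kB)` trials.  This ignores dependence between overlapping
#' neighbourhoods and is reported as an indicative approximation only.
#'
#' @param counts a `binomial_counts` object.
#' @param d_hat the dimension estimate.
#' @export
abide_std <- function(counts, d_hat) {
  if (d_hat <= 0) stop("d_hat must be positive")
  p <- counts$tau^d_hat
  if (p <= .Machine$double.eps || p >= 1 - .Machine$double.eps)
    stop("binomial success probability numerically degenerate")
  sqrt((1 - p) / (p * sum(counts$kB) * log(counts$tau)^2))
}

#' Joint estimation of intrinsic dimension and adaptive neighbourhoods
#'
#' Iterates (shell volumes at the current dimension) -> (likelihood-ratio
#' neighbourhood scan) -> (concentric-ball counts) -> (binomial dimension
#' estimate) until the dimension changes by at most `tol`, starting from a
#' binomial estimate on a fixed small neighbourhood.  Returns the
#' real-valued estimate `d_hat`, its nearest integer `d_star` (half away
#' from zero), an approximate standard deviation, the per-iteration trace,
#' and the per-point neighbourhood sizes `k_star` of the final iteration.
#'
#' The procedure is deterministic given its inputs.  If the iteration
#' oscillates without meeting `tol` within `max_iter` sweeps, the average
#' of the last two iterates is returned with `converged = FALSE` and a
#' warning (never an error).
#'
#' @param X numeric data matrix (n x D), or `NULL` when `neighbors` is
#'   supplied.
#' @param tau radius ratio of the concentric balls, in (0, 1).
#' @param alpha level of the homogeneity test, in (0, 1).
#' @param k_min first neighbour order tested by the scan.
#' @param k_max largest neighbourhood considered,
#'   default `min(n - 1, 100)`.
#' @param d_init optional initial dimension; by default a binomial
#'   estimate on a fixed neighbourhood of size `min(10, k_max)`.
#' @param tol convergence tolerance on successive dimension estimates.
#' @param max_iter iteration cap.
#' @param neighbors optionally a precomputed [neighbor_table()] (with
#'   `k_max` columns at least).
#' @return class `abide`: list with `estimate` (class `id_estimate`:
#'   `d_hat`, `d_star`, `std`, `trace`, `converged`, `iterations`, `tau`,
#'   `alpha`), `neighborhood` (class `adaptive_neighborhood`), `counts`,
#'   `neighbors`, and `params`.
#' @export
#' @examples
#' fit <- abide(as.matrix(iris[, 1:4]))
#' fit$estimate$d_hat
abide <- function(X = NULL, tau = 0.5, alpha = 0.01, k_min = 3L,
                  k_max = NULL, d_init = NULL, tol = 1e-3,
                  max_iter = 50L, neighbors = NULL) {
  if (tau <= 0 || tau >= 1) stop("tau must be in (0, 1)")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (is.null(neighbors)) {
    X <- check_data_matrix(X)
    k_max <- as.integer(k_max %||% min(nrow(X) - 1L, 100L))
    neighbors <- neighbor_table(X, k_max)
  } else {
    stopifnot(inherits(neighbors, "neighbor_table"))
    k_max <- as.integer(k_max %||% neighbors$k_max)
    k_max <- min(k_max, neighbors$k_max)
  }
  if (is.null(d_init)) {
    K0 <- fixed_neighborhood(neighbors, min(10L, k_max))
    d_init <- bide_estimate(counts_from_kstar(neighbors, K0, tau))
    if (!is.finite(d_init) || d_init <= 0) d_init <- 1
  }
  d <- d_init
  trace <- d
  converged <- FALSE
  K <- NULL
  counts <- NULL
  for (it in seq_len(max_iter)) {
    K <- select_kstar(neighbors, d, alpha = alpha, k_min = k_min,
                      k_max = k_max)
    counts <- counts_from_kstar(neighbors, K, tau)
    d_new <- bide_estimate(counts)
    trace <- c(trace, d_new)
    if (abs(d_new - d) <= tol) {
      d <- d_new
      converged <- TRUE
      break
    }
    d <- d_new
  }
  if (!converged) {
    d <- mean(trace[length(trace) - 0:1])
    warning("dimension iteration did not converge in ", max_iter,
            " sweeps; returning the average of the last two iterates")
  }
  est <- structure(
    list(d_hat = d, d_star = as.integer(round_half_away(d)),
         std = abide_std(counts, d), trace = trace,
         converged = converged, iterations = length(trace) - 1L,
         tau = tau, alpha = alpha),
    class = "id_estimate")
  structure(list(estimate = est, neighborhood = K, counts = counts,
                 neighbors = neighbors,
                 params = list(tau = tau, alpha = alpha, k_min = k_min,
                               k_max = k_max, tol = tol,
                               max_iter = max_iter, d_init = d_init)),
            class = "abide")
}

#' @export
print.id_estimate <- function(x, ...) {
  cat(sprintf("intrinsic dimension: d_hat = %.3f (d* = %d, std ~ %.3f)\n",
              x$d_hat, x$d_star, x$std))
  cat(sprintf("  %d iteration(s), converged: %s\n", x$iterations,
              x$converged))
  invisible(x)
}

#' @export
print.abide <- function(x, ...) {
  print(x$estimate)
  print(x$neighborhood)
  invisible(x)
}
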