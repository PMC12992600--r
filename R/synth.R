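#' Synthetic manifold benchmark generator
#'
#' Samples points uniformly (by surface area where the naive parameter
#' chart is non-uniform) on up to three manifolds in 3-D — a torus, a
#' spiral and a sphere — perturbs the three manifold coordinates with
#' Gaussian noise, and pads the ambient space with pure-noise Gaussian
#' coordinates up to `ambient_dim`.  With the default three shapes at
#' 1700 points each the dataset has 5100 observations in 20 dimensions
#' and a de-noised intrinsic dimension of 3 (two-dimensional surfaces and
#' a one-dimensional curve thickened by the 3-D noise).
#'
#' The torus is sampled with rejection in the poloidal angle so the
#' surface density is uniform (naive angle sampling over-represents the
#' inner rim); the sphere by normalised Gaussians; the spiral uniformly
#' in its parameter.
#'
#' @param n_per_shape points per shape (recycled over `shapes`).
#' @param shapes subset of `"torus"`, `"spiral"`, `"sphere"`.
#' @param ambient_dim total number of coordinates (>= 3).
#' @param noise_sd standard deviation of the Gaussian perturbation of the
#'   3 manifold coordinates.
#' @param extra_noise_sd standard deviation of the `ambient_dim - 3`
#'   pure-noise coordinates.
#' @param torus_radii `c(R, r)`: centre-line and tube radii, `r < R`.
#' @param sphere_radius sphere radius.
#' @param spiral_t_max spiral parameter range `[0, spiral_t_max]`.
#' @param spiral_scale scale applied to the spiral coordinates
#'   `(t cos t, t sin t, t)`.
#' @param seed RNG seed; same seed, same dataset.
#' @return class `manifold_data`: list with `X`
#'   (n x `ambient_dim` matrix), integer `labels` (shape membership,
#'   1-based) and `clean` (the unperturbed 3-D coordinates).
#' @export
#' @examples
#' md <- generate_manifolds(n_per_shape = 50, seed = 1)
#' dim(md$X)  # 150 x 20
generate_manifolds <- function(n_per_shape = 1700L,
                               shapes = c("torus", "spiral", "sphere"),
                               ambient_dim = 20L, noise_sd = 0.035,
                               extra_noise_sd = 0.035,
                               torus_radii = c(2, 0.5),
                               sphere_radius = 1,
                               spiral_t_max = 4 * pi,
                               spiral_scale = 1 / (2 * pi),
                               seed = NULL) {
  shapes <- match.arg(shapes, several.ok = TRUE)
  if (ambient_dim < 3L) stop("ambient_dim must be >= 3")
  if (torus_radii[2] >= torus_radii[1])
    stop("invalid geometry: torus tube radius must be smaller than the ",
         "centre-line radius")
  if (noise_sd < 0 || extra_noise_sd < 0) stop("noise sd must be >= 0")
  n_per_shape <- rep_len(as.integer(n_per_shape), length(shapes))
  if (!is.null(seed)) set.seed(seed)
  parts <- vector("list", length(shapes))
  for (s in seq_along(shapes)) {
    m <- n_per_shape[s]
    parts[[s]] <- switch(shapes[s],
      torus = sample_torus(m, torus_radii[1], torus_radii[2]),
      spiral = {
        t <- runif(m, 0, spiral_t_max)
        cbind(t * cos(t), t * sin(t), t) * spiral_scale
      },
      sphere = {
        g <- matrix(rnorm(m * 3L), m, 3L)
        sphere_radius * g / sqrt(rowSums(g^2))
      })
  }
  clean <- do.call(rbind, parts)
  n <- nrow(clean)
  labels <- rep.int(seq_along(shapes), n_per_shape)
  X <- clean
  if (noise_sd > 0)
    X <- X + matrix(rnorm(n * 3L, sd = noise_sd), n, 3L)
  if (ambient_dim > 3L) {
    extra <- matrix(0, n, ambient_dim - 3L)
    if (extra_noise_sd > 0)
      extra <- matrix(rnorm(n * (ambient_dim - 3L), sd = extra_noise_sd),
                      n, ambient_dim - 3L)
    X <- cbind(X, extra)
  }
  structure(list(X = X, labels = as.integer(labels), clean = clean,
                 spec = list(shapes = shapes, n_per_shape = n_per_shape,
                             ambient_dim = ambient_dim,
                             noise_sd = noise_sd,
                             extra_noise_sd = extra_noise_sd,
                             torus_radii = torus_radii,
                             sphere_radius = sphere_radius,
                             spiral_t_max = spiral_t_max,
                             spiral_scale = spiral_scale, seed = seed)),
            class = "manifold_data")
}

## uniform-by-area torus sampling: accept poloidal angle v with
## probability proportional to R + r cos(v)
sample_torus <- function(m, R, r) {
  out <- matrix(0, 0L, 3L)
  while (nrow(out) < m) {
    draw <- max(2L * (m - nrow(out)), 16L)
    u <- runif(draw, 0, 2 * pi)
    v <- runif(draw, 0, 2 * pi)
    acc <- runif(draw) < (R + r * cos(v)) / (R + r)
    u <- u[acc]; v <- v[acc]
    out <- rbind(out, cbind((R + r * cos(v)) * cos(u),
                            (R + r * cos(v)) * sin(u),
                            r * sin(v)))
  }
  out[seq_len(m), , drop = FALSE]
}

#' @export
print.manifold_data <- function(x, ...) {
  cat("manifold_data:", nrow(x$X), "x", ncol(x$X), "points on",
      paste(x$spec$shapes, collapse = "/"), "\n")
  invisible(x)
}
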