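# Barycentric weights have closed forms in 1-D; embeddings are checked
# against exactly recoverable geometries (affine planes, arcs) up to
# orthogonal alignment.

test_that("local weights: closed 1-D cases and the sum constraint", {
  expect_equal(local_weights(cbind(c(5, 7)), 1, 2), 1)
  expect_equal(local_weights(cbind(c(0, -1, 1)), 1, c(2, 3)),
               c(0.5, 0.5))
  expect_equal(local_weights(cbind(c(1, 0, 4)), 1, c(2, 3)),
               c(0.75, 0.25))
  set.seed(19)
  X <- matrix(rnorm(50 * 4), 50, 4)
  for (i in c(1, 25)) {
    w <- local_weights(X, i, setdiff(1:15, i))
    expect_equal(sum(w), 1, tolerance = 1e-12)
  }
  expect_error(local_weights(X, 1, integer(0)), "empty")
  expect_error(local_weights(X, 1, c(1, 2)), "own neighbour")
})

test_that("coincident neighbourhoods fall back to uniform weights", {
  X <- rbind(c(1, 1), c(1, 1), c(1, 1))
  expect_equal(local_weights(X, 1, c(2, 3)), c(0.5, 0.5))
})

test_that("weight matrix: row-stochastic on the adjacency support", {
  set.seed(20)
  X <- matrix(rnorm(60 * 3), 60, 3)
  nt <- neighbor_table(X, 12)
  K <- select_kstar(nt, 3)
  A <- adaptive_adjacency(nt, K)
  W <- assemble_weight_matrix(X, A)
  expect_equal(as.numeric(Matrix::rowSums(W$W)), rep(1, 60),
               tolerance = 1e-10)
  # support containment
  expect_true(all((W$W != 0) * 1 <= as.matrix(A$W)))
  # 3-point line: point 1 has the single neighbour 2 with weight 1
  nt3 <- neighbor_table(cbind(c(0, 1, 3)), 2)
  K3 <- structure(list(k_star = c(1L, 1L, 2L), capped = rep(FALSE, 3),
                       alpha = NA_real_, D_thr = NA_real_, k_min = 1L,
                       k_max = 2L),
                  class = "adaptive_neighborhood")
  W3 <- assemble_weight_matrix(cbind(c(0, 1, 3)),
                               adaptive_adjacency(nt3, K3))
  expect_equal(as.matrix(W3$W)[1, ], c(0, 1, 0))
})

test_that("embedding satisfies the centering and covariance constraints", {
  pl <- make_plane(150, D = 5, seed = 4)
  m <- lle_star(pl$X, d_proj = 2)
  Y <- m$embedding$Y
  expect_lt(max(abs(colMeans(Y))), 1e-8)
  expect_lt(max(abs(crossprod(Y) / nrow(Y) - diag(2))), 1e-8)
})

test_that("an affine plane is recovered up to orthogonal alignment", {
  pl <- make_plane(220, D = 6, seed = 5)
  m <- lle_star(pl$X, d_proj = 2, n_neighbors = 8)
  expect_lt(m$embedding$cost, 1e-3)
  ## the embedding is unit-covariance by construction, so whiten the
  ## latent coordinates before the orthogonal alignment
  lat <- scale(pl$latent, center = TRUE, scale = FALSE)
  lat <- lat %*% solve(chol(crossprod(lat) / nrow(lat)))
  expect_lt(procrustes_error(m$embedding$Y, lat), 1e-3)
})

test_that("embedding cost equals n times the retained eigenvalues and is
           rotation invariant", {
  set.seed(23)
  X <- cbind(matrix(rnorm(120 * 3), 120, 3), matrix(0, 120, 2))
  m <- lle_star(X, d_proj = 2, n_neighbors = 8)
  W <- m$weights$W
  Y <- m$embedding$Y
  resid <- Y - as.matrix(W %*% Y)
  expect_equal(sum(resid^2), m$embedding$cost, tolerance = 1e-6)
  Q <- random_rotation(5, seed = 6)
  mq <- lle_star(X %*% Q, d_proj = 2, n_neighbors = 8)
  expect_equal(mq$embedding$cost, m$embedding$cost, tolerance = 1e-6)
})

test_that("a 1-D embedding of a noiseless arc is monotone in arc length", {
  set.seed(24)
  t <- sort(runif(150, 0, pi))            # ordered circular arc
  X <- cbind(cos(t), sin(t))
  ## on a curve the regularised reconstruction follows the manifold
  ## rather than interpolating in the ambient plane
  m <- lle_star(X, d_proj = 1, n_neighbors = 6)
  y <- m$embedding$Y[, 1]
  expect_true(all(diff(y) > 0) || all(diff(y) < 0))
})

test_that("out-of-sample projection: linearity and training consistency", {
  pl <- make_plane(200, D = 5, seed = 7)
  m <- lle_star(pl$X, d_proj = 2)
  # a training point projects near its own embedding
  y_dup <- predict(m, pl$X[17, ])
  expect_lt(sqrt(sum((y_dup - m$embedding$Y[17, ])^2)), 0.15)
  # barycentre linearity: if the solver returns weights w on neighbours,
  # the projection is exactly the weighted neighbour barycentre
  q <- adaptdr:::query_distances(m$X, pl$X[17, ] + 1e-3)
  kq <- 5L
  nbrs <- q$indices[seq_len(kq)]
  w <- local_weights(rbind(pl$X[17, ] + 1e-3, m$X), 1L, nbrs + 1L)
  y_manual <- as.numeric(crossprod(m$embedding$Y[nbrs, ], w))
  m_fixed <- lle_star(pl$X, d_proj = 2, n_neighbors = kq)
  y_pkg <- predict(m_fixed, pl$X[17, ] + 1e-3)
  w_f <- local_weights(rbind(pl$X[17, ] + 1e-3, m_fixed$X), 1L, nbrs + 1L)
  expect_equal(as.numeric(y_pkg),
               as.numeric(crossprod(m_fixed$embedding$Y[nbrs, ], w_f)),
               tolerance = 1e-10)
  expect_error(predict(m, rnorm(7)), "dimension mismatch")
})

test_that("disconnected graphs embed the largest component with NA rest", {
  X <- rbind(matrix(rnorm(60, sd = 0.2), 30, 2),
             matrix(rnorm(12, sd = 0.2) + 100, 6, 2))
  expect_warning(m <- lle_star(X, d_proj = 1, n_neighbors = 3),
                 "disconnected")
  expect_true(all(is.na(m$embedding$Y[31:36, ])))
  expect_false(anyNA(m$embedding$Y[1:30, ]))
})
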