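# The deviance statistic and the binomial dimension estimate both have
# closed forms; the tests here check them against direct numerical
# likelihood maximisation, and check the iterative estimator against
# samples of known intrinsic dimension.

test_that("unit ball volumes: closed values and fractional dimension", {
  expect_equal(unit_ball_volume(1), 2)
  expect_equal(unit_ball_volume(2), pi)
  expect_equal(unit_ball_volume(3), 4 * pi / 3)
  # pi^1.25 / gamma(2.25), frozen from an independent Gamma evaluation
  expect_equal(unit_ball_volume(2.5), 3.69152865686496, tolerance = 1e-13)
  expect_error(unit_ball_volume(0), "positive")
  expect_error(unit_ball_volume(-1), "positive")
})

test_that("shell volumes: disc areas, zero shells, telescoping", {
  X <- cbind(c(0, 1, -2))   # point 1 has neighbour radii 1, 2
  nt <- neighbor_table(X, 2)
  sv <- shell_volumes(nt, 2)
  expect_equal(sv$v[1, ], c(pi, 3 * pi))
  expect_equal(sv$V[1, ], c(pi, 4 * pi))

  # duplicate points give zero-volume shells
  X2 <- rbind(c(0, 0), c(1, 0), c(1, 0), c(3, 0))
  nt2 <- neighbor_table(X2, 3)
  sv2 <- shell_volumes(nt2, 2)
  expect_equal(sv2$v[1, 2], 0)  # radii 1, 1 -> empty shell

  # cumulative volume telescopes to the full ball at the k-th radius
  set.seed(42)
  X3 <- matrix(rnorm(30 * 3), 30, 3)
  nt3 <- neighbor_table(X3, 10)
  sv3 <- shell_volumes(nt3, 3)
  expect_equal(sv3$V[, 10], unit_ball_volume(3) * nt3$distances[, 10]^3,
               tolerance = 1e-10)
})

## numerically maximise the two exponential log-likelihoods with common
## vs separate intensities; the deviance is the oracle for lrt_statistic
lrt_numeric <- function(V_i, V_j, k) {
  ll <- function(rho, V) k * log(rho) - rho * V
  h1 <- optimize(function(r) ll(r, V_i), c(1e-12, 1e6),
                 maximum = TRUE, tol = 1e-12)$objective +
        optimize(function(r) ll(r, V_j), c(1e-12, 1e6),
                 maximum = TRUE, tol = 1e-12)$objective
  h0 <- optimize(function(r) ll(r, V_i) + ll(r, V_j), c(1e-12, 1e6),
                 maximum = TRUE, tol = 1e-12)$objective
  -2 * (h0 - h1)
}

test_that("deviance statistic: hand values and numerical maximisation", {
  expect_equal(lrt_statistic(1, 1, 5), 0)
  expect_equal(lrt_statistic(2.7, 2.7, 12), 0)
  expect_equal(lrt_statistic(1, 3, 5), 10 * log(4 / 3))
  expect_equal(lrt_statistic(1, 10, 1), 2 * log(121 / 40))
  expect_equal(lrt_statistic(1, 3, 5), lrt_numeric(1, 3, 5),
               tolerance = 1e-8)
  expect_error(lrt_statistic(0, 1, 3), "degenerate shells")
  set.seed(7)
  for (r in 1:20) {
    V_i <- runif(1, 0.05, 5); V_j <- runif(1, 0.05, 5)
    k <- sample(1:30, 1)
    expect_gte(lrt_statistic(V_i, V_j, k), 0)
  }
})

test_that("neighbourhood scan: threshold, monotonicity in alpha, capping", {
  set.seed(8)
  X <- matrix(runif(300 * 2), 300, 2)
  nt <- neighbor_table(X, 40)
  K <- select_kstar(nt, 2, alpha = 0.05, keep_statistics = TRUE)
  expect_equal(K$D_thr, qchisq(0.95, 1))
  # first-crossing rule agrees with the stored deviance sequence
  for (i in c(1, 57, 200)) {
    s <- K$statistics[i, ]
    hit <- which(!is.na(s) & s >= K$D_thr)
    expect_equal(K$k_star[i], if (length(hit)) min(hit) else nt$k_max)
  }
  # smaller alpha (higher threshold) never shrinks neighbourhoods
  K2 <- select_kstar(nt, 2, alpha = 0.001)
  expect_true(all(K2$k_star >= K$k_star))
  # an astronomically high threshold caps every point
  K3 <- select_kstar(nt, 2, alpha = 1e-15)
  expect_true(all(K3$capped))
  expect_true(all(K3$k_star == nt$k_max))
  expect_error(select_kstar(nt, 2, alpha = 1.2), "alpha")
})

test_that("binomial dimension estimate equals the likelihood argmax", {
  counts <- list(kA = 25, kB = 100, tau = 0.5)
  expect_identical(bide_estimate(counts), 2)
  expect_equal(bide_estimate(list(kA = c(5, 5), kB = c(5, 5),
                                  tau = 0.3)), 0)
  # golden-section argmax of the printed binomial likelihood
  set.seed(9)
  for (r in 1:5) {
    kB <- sample(20:80, 10, replace = TRUE)
    kA <- rbinom(10, kB, 0.3)
    if (sum(kA) == 0) kA[1] <- 1
    tau <- runif(1, 0.3, 0.7)
    loglik <- function(d)
      sum(kA) * d * log(tau) + sum(kB - kA) * log(1 - tau^d)
    opt <- optimize(loglik, c(1e-6, 60), maximum = TRUE, tol = 1e-10)
    expect_equal(bide_estimate(list(kA = kA, kB = kB, tau = tau)),
                 opt$maximum, tolerance = 1e-6)
  }
  expect_error(bide_estimate(list(kA = 0, kB = 10, tau = 0.5)),
               "empty inner balls")
})

test_that("binomial estimate is consistent under the generative model", {
  set.seed(123)
  kB <- rep(50L, 4000)
  kA <- rbinom(length(kB), kB, 0.5^3)
  d_hat <- bide_estimate(list(kA = kA, kB = kB, tau = 0.5))
  expect_equal(d_hat, 3, tolerance = 0.05)
})

test_that("concentric-ball counts from the adaptive neighbourhoods", {
  # hand case: distances 1,2,3,4, k* = 4, tau = 0.5
  X <- cbind(c(0, 1, 2, 3, 4))
  nt <- neighbor_table(X, 4)
  K <- fixed_neighborhood(nt, 4)
  cts <- counts_from_kstar(nt, K, 0.5)
  expect_equal(cts$kA[1], 2)  # r_A = 2; neighbours at 1, 2 counted (<=)
  expect_equal(cts$kB[1], 4)
  # tau -> 1: every neighbour falls inside the inner ball
  cts1 <- counts_from_kstar(nt, K, 1 - 1e-12)
  expect_true(all(cts1$kA == cts1$kB))
  # random data: kA equals a brute-force radius count
  set.seed(21)
  Xr <- matrix(rnorm(80 * 3), 80, 3)
  ntr <- neighbor_table(Xr, 15)
  Kr <- fixed_neighborhood(ntr, 15)
  ctr <- counts_from_kstar(ntr, Kr, 0.6)
  Dm <- as.matrix(dist(Xr)); diag(Dm) <- Inf
  for (i in c(3, 40, 80)) {
    rB <- ntr$distances[i, 15]
    expect_equal(ctr$kA[i], sum(Dm[i, ] <= 0.6 * rB))
  }
  # zero outer radius -> exclusion with a warning
  Xd <- rbind(c(0, 0), c(0, 0), c(9, 9))
  ntd <- neighbor_table(Xd, 1)
  expect_warning(ctd <- counts_from_kstar(ntd, fixed_neighborhood(ntd, 1),
                                          0.5),
                 "zero outer radius")
  expect_length(ctd$kA, 1)   # only the isolated point survives
})

test_that("delta-method standard deviation: value and scaling", {
  cts <- list(kA = 25, kB = rep(100, 100), tau = 0.5)  # sum kB = 10000
  expect_equal(abide_std(cts, 2),
               sqrt(0.75 / (0.25 * 10000 * log(0.5)^2)),
               tolerance = 1e-12)
  expect_equal(abide_std(cts, 2), 0.0250, tolerance = 1e-3)
  cts2 <- list(kA = 25, kB = rep(100, 200), tau = 0.5)
  expect_equal(abide_std(cts, 2) / abide_std(cts2, 2), sqrt(2),
               tolerance = 1e-12)
  expect_error(abide_std(list(kA = 1, kB = 10, tau = 0.5), 1e6),
               "degenerate")
})

test_that("iterative estimator recovers known dimensions", {
  set.seed(31)
  # 2-D hypercube in 8 ambient dimensions
  X <- cbind(matrix(runif(900 * 2), 900, 2), matrix(0, 900, 6))
  f <- abide(X)
  expect_equal(f$estimate$d_star, 2L)
  expect_true(f$estimate$converged)
  expect_equal(f$estimate$d_star,
               as.integer(round(f$estimate$d_hat)))
  expect_gte(length(f$estimate$trace), 2)
})

test_that("estimator is invariant to row permutation and rotation", {
  set.seed(33)
  X <- cbind(matrix(runif(300 * 2), 300, 2), matrix(0, 300, 3))
  f <- abide(X, k_max = 40)
  perm <- sample(300)
  fp <- abide(X[perm, ], k_max = 40)
  expect_equal(fp$estimate$d_hat, f$estimate$d_hat, tolerance = 1e-12)
  expect_equal(fp$neighborhood$k_star[order(perm)],
               f$neighborhood$k_star)
  Q <- random_rotation(5, seed = 2)
  fr <- abide(X %*% Q, k_max = 40)
  expect_equal(fr$estimate$d_hat, f$estimate$d_hat, tolerance = 1e-8)
})

test_that("non-convergence returns the averaged iterate with a warning", {
  set.seed(35)
  X <- matrix(rnorm(200 * 5), 200, 5)
  expect_warning(f <- abide(X, max_iter = 1L, tol = 0),
                 "did not converge")
  expect_false(f$estimate$converged)
  expect_equal(f$estimate$d_hat,
               mean(utils::tail(f$estimate$trace, 2)))
})
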