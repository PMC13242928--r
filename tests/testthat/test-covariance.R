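test_that("perfectly concordant genes give tau = 1 under uniform weights", {
  vals <- cbind(m = c(1, 2, 3, 4), n = c(2, 4, 5, 9))
  expr <- expression_matrix(vals)
  kern <- cellgrn:::uniform_kernel(4)
  nbrs <- neighbor_sets(kern, 4, 4)
  tau <- weighted_kendall_tau(expr, kern, nbrs, 1)
  expect_equal(tau[1, 2], 1)
  expect_equal(tau[2, 1], 1)
})

test_that("an all-zero gene annihilates its tau rows", {
  vals <- cbind(c(1, 2, 3), c(0, 0, 0), c(3, 1, 2))
  expr <- expression_matrix(vals)
  kern <- cellgrn:::uniform_kernel(3)
  nbrs <- neighbor_sets(kern, 3, 3)
  tau <- weighted_kendall_tau(expr, kern, nbrs, 1)
  expect_equal(tau[2, ], rep(0, 3))
  expect_equal(tau[, 2], rep(0, 3))
})

test_that("weighted tau matches the quadruple-loop oracle on random fixtures", {
  set.seed(99)
  for (rep in 1:50) {
    n <- sample(3:8, 1)
    g <- sample(2:5, 1)
    vals <- matrix(rexp(n * g), n, g)
    vals[matrix(runif(n * g) < 0.25, n, g)] <- 0   # zero annotations
    expr <- expression_matrix(vals)
    # a valid random kernel: symmetric, unit diagonal, entries in (0, 1]
    D <- as.matrix(dist(matrix(rnorm(n * 2), n, 2)))
    kern <- cellgrn:::kernel_from_distances(D, sigma = runif(1, 0.5, 2))
    Nj <- sample(2:n, 1)
    nbrs <- neighbor_sets(kern, n_objective = Nj, n_covariance = Nj)
    j <- sample(n, 1)
    tau <- weighted_kendall_tau(expr, kern, nbrs, j)
    tau_oracle <- oracle_kendall_tau(expr$values, kern$K,
                                     nbrs$covariance_neighbors[j, ])
    expect_equal(tau, tau_oracle, tolerance = 1e-12)
    expect_true(all(abs(tau) <= 1 + 1e-12))
  }
})

test_that("with unit weights and no zeros tau reduces to classical Kendall", {
  set.seed(5)
  n <- 8
  vals <- matrix(rexp(n * 3) + 0.01, n, 3)
  expr <- expression_matrix(vals)
  kern <- cellgrn:::uniform_kernel(n)
  nbrs <- neighbor_sets(kern, n, n)
  tau <- weighted_kendall_tau(expr, kern, nbrs, 1)
  for (m in 1:2) for (q in (m + 1):3) {
    classical <- cor(vals[, m], vals[, q], method = "kendall")
    expect_equal(tau[m, q], classical, tolerance = 1e-12)
  }
})

test_that("sine transform maps tau to latent Pearson correlation", {
  expect_equal(tau_to_covariance(matrix(c(0, 1, 1, 0), 2))[1, 2], 1)
  expect_equal(tau_to_covariance(matrix(0, 2, 2))[1, 2], 0)
  expect_equal(diag(tau_to_covariance(matrix(0.3, 3, 3))), rep(1, 3))
  expect_error(tau_to_covariance(matrix(c(0, 1.1, 1.1, 0), 2)), "outside")
  # Greiner identity: for bivariate Gaussian, sin(pi/2 tau) recovers rho
  set.seed(21)
  rho <- 0.6
  nS <- 2000
  z <- matrix(rnorm(2 * nS), nS, 2) %*% chol(matrix(c(1, rho, rho, 1), 2))
  expr <- expression_matrix(z, check_nonneg = FALSE)
  kern <- cellgrn:::uniform_kernel(nS)
  nbrs <- neighbor_sets(kern, 2, nS)
  tau <- weighted_kendall_tau(expr, kern, nbrs, 1)
  est <- tau_to_covariance(tau)[1, 2]
  expect_lt(abs(est - rho), 0.05)
})

test_that("positive-definite projection floors bad eigenvalues and is idempotent", {
  expect_identical(project_positive_definite(diag(3)), diag(3))
  out <- project_positive_definite(diag(c(2, -0.5)))
  expect_equal(sort(eigen(out, only.values = TRUE)$values), c(1e-3, 2))
  set.seed(31)
  for (rep in 1:5) {
    A <- matrix(rnorm(25), 5, 5)
    S <- (A + t(A)) / 2   # indefinite in general
    P <- project_positive_definite(S)
    ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), 1e-3 - 1e-9)
    # unchanged on the span of positive-eigenvalue eigenvectors
    e <- eigen(S, symmetric = TRUE)
    pos <- e$values > 0
    if (any(pos)) {
      V <- e$vectors[, pos, drop = FALSE]
      expect_equal(t(V) %*% P %*% V, t(V) %*% S %*% V, tolerance = 1e-8)
    }
    # idempotent
    expect_equal(project_positive_definite(P), P, tolerance = 1e-10)
  }
  expect_error(project_positive_definite(matrix(c(1, 2, 0, 1), 2)),
               "symmetric")
})

test_that("per-cell covariances compose the three single operations", {
  expr <- toy_expression(n = 6, g = 4, seed = 13)
  coords <- spatial_coordinates(cbind(seq_len(6), 0))
  kern <- spatial_kernel(coords, k = 2, sigma = 2)
  nbrs <- neighbor_sets(kern, 4, 4)
  cov <- cell_covariances(expr, kern, nbrs, epsilon = 1e-3)
  for (j in 1:6) {
    manual <- project_positive_definite(
      tau_to_covariance(weighted_kendall_tau(expr, kern, nbrs, j)), 1e-3)
    expect_equal(cov$Sigma[j, , ], manual, tolerance = 1e-12)
    ev <- eigen(cov$Sigma[j, , ], symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), 1e-3 - 1e-9)
  }
})

test_that("identical expression across cells gives identical covariances", {
  vals <- matrix(rep(c(1, 0, 2, 3), each = 5), 5, 4)
  expr <- expression_matrix(vals)
  kern <- cellgrn:::uniform_kernel(5)
  nbrs <- neighbor_sets(kern, 5, 5)
  cov <- cell_covariances(expr, kern, nbrs)
  for (j in 2:5) expect_equal(cov$Sigma[j, , ], cov$Sigma[1, , ])
})

test_that("a single-cell neighbourhood is rejected", {
  expr <- toy_expression(n = 3, g = 3)
  kern <- cellgrn:::uniform_kernel(3)
  expect_error(neighbor_sets(kern, 1, 1), "n_covariance")
})
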