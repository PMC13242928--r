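no_mask <- function(g) matrix(0, g, g)

test_that("unpenalized solve recovers the closed-form inverse", {
  # identity data -> identity precision
  res <- admm_solve(diag(4), no_mask(4), solver_config(lam = 0, beta = 0))
  expect_equal(res$theta, diag(4), tolerance = 1e-5)
  expect_true(res$converged)
  # any PD matrix -> its inverse
  set.seed(8)
  for (rep in 1:5) {
    S <- random_corr_pd(5)
    res <- admm_solve(S, no_mask(5),
                      solver_config(lam = 0, beta = 0, max_iter = 20000,
                                    tol_primal = 1e-10, tol_dual = 1e-10))
    expect_lt(sqrt(sum((res$theta - solve(S))^2)), 1e-4)
  }
})

test_that("l1-penalized solve agrees with the coordinate-descent oracle", {
  set.seed(17)
  for (g in c(5, 6)) for (lam in c(0.05, 0.1, 0.2)) {
    S <- random_corr_pd(g)
    res <- admm_solve(S, no_mask(g),
                      solver_config(lam = lam, beta = 0, max_iter = 5000,
                                    tol_primal = 1e-8, tol_dual = 1e-8))
    ref <- oracle_glasso(S, lam)
    expect_lt(sqrt(sum((res$theta - ref)^2)), 1e-4)
  }
})

test_that("every Theta iterate stays positive definite", {
  set.seed(23)
  for (rep in 1:20) {
    g <- sample(3:8, 1)
    S <- random_corr_pd(g)
    lam <- runif(1, 0, 0.3)
    beta <- sample(c(0, 1, 100), 1)
    M <- no_mask(g)
    if (beta > 0) {
      M[1, 2] <- M[2, 1] <- 1
    }
    res <- admm_solve(S, M, solver_config(lam = lam, beta = beta,
                                          max_iter = 200),
                      track_pd = TRUE)
    expect_true(all(res$theta_min_eigen > 0))
  }
})

test_that("edge count is non-increasing in the sparsity penalty", {
  set.seed(29)
  S <- random_corr_pd(8)
  counts <- vapply(c(0.01, 0.05, 0.1, 0.2, 0.4), function(lam) {
    res <- admm_solve(S, no_mask(8), solver_config(lam = lam, beta = 0))
    sum(abs(res$Z[upper.tri(res$Z)]) > 1e-4)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("masked entries vanish monotonically as beta grows", {
  set.seed(37)
  S <- random_corr_pd(6)
  M <- no_mask(6)
  M[1, 2] <- M[2, 1] <- M[3, 5] <- M[5, 3] <- 1
  mags <- vapply(c(0, 1, 10, 100, 1e4), function(beta) {
    res <- admm_solve(S, M, solver_config(lam = 0.01, beta = beta))
    max(abs(res$theta[M == 1]))
  }, numeric(1))
  expect_true(all(diff(mags) <= 1e-10))
  # at beta = 1e4 the masked entries are negligible relative to the rest
  res <- admm_solve(S, M, solver_config(lam = 0.01, beta = 1e4))
  expect_lt(max(abs(res$theta[M == 1])), 1e-3 * max(abs(res$theta)))
})

test_that("the argmin is invariant to positive rescaling of the objective", {
  # raw-scale solve with lam, beta premultiplied by |Ni| W / 2 equals the
  # normalized solve with lam, beta as given
  set.seed(41)
  expr <- toy_expression(n = 8, g = 5, seed = 41, zero_frac = 0.1)
  kern <- expression_kernel(expr, n_pcs = 3, k = 3)
  nbrs <- neighbor_sets(kern, 5, 5)
  cov <- cell_covariances(expr, kern, nbrs)
  prior <- prior_from_tf_list(c("gene_1", "gene_2"), expr$gene_names, 8)
  dat1 <- assemble_cell_data(kern, nbrs, cov, 1)
  scale1 <- dat1$n_objective * dat1$W / 2
  # verbatim-scale run whose penalties are premultiplied by the cell's
  # neighbourhood mass: cell 1 must match the normalized solve exactly
  fit_raw <- infer_all_cells(expr, kern, nbrs, cov, prior,
                             solver_config(lam = 0.05 * scale1,
                                           beta = 1 * scale1,
                                           raw_scale = TRUE))
  M_1 <- prior$M[1, , ]; diag(M_1) <- 0
  res_norm <- admm_solve(dat1$S_bar, M_1, solver_config(lam = 0.05, beta = 1))
  expect_equal(fit_raw$networks[1, , ], res_norm$theta, tolerance = 1e-10)
})

test_that("assemble_cell_data averages neighbourhood covariances by kernel weight", {
  expr <- toy_expression(n = 3, g = 3, seed = 3, zero_frac = 0)
  D <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3)
  kern <- cellgrn:::kernel_from_distances(D, sigma = 1)
  nbrs <- neighbor_sets(kern, 3, 3)
  cov <- cell_covariances(expr, kern, nbrs)
  dat <- assemble_cell_data(kern, nbrs, cov, 1)
  w <- kern$K[1, nbrs$objective_neighbors[1, ]]
  manual <- matrix(0, 3, 3)
  for (t in 1:3)
    manual <- manual + w[t] * cov$Sigma[nbrs$objective_neighbors[1, t], , ]
  manual <- manual / sum(w)
  expect_equal(dat$S_bar, manual, tolerance = 1e-12)
  expect_equal(dat$W, sum(w))
  # single-cell neighbourhood: S_bar is that cell's covariance
  nbrs1 <- neighbor_sets(kern, 1, 3)
  dat1 <- assemble_cell_data(kern, nbrs1, cov, 2)
  expect_equal(dat1$S_bar, cov$Sigma[2, , ])
  expect_equal(dat1$W, 1)
  # equal weights on two equal matrices -> their average
  cov2 <- cov
  A <- cov$Sigma[1, , ]; B <- cov$Sigma[3, , ]
  cov2$Sigma[2, , ] <- A
  cov2$Sigma[3, , ] <- B
  nbrs2 <- list(objective_neighbors = matrix(c(2L, 3L), 1, 2, byrow = TRUE))
  kern_u <- cellgrn:::uniform_kernel(3)
  dat2 <- assemble_cell_data(kern_u, structure(nbrs2, class = "cg_neighbors"),
                             cov2, 1)
  expect_equal(dat2$S_bar, (A + B) / 2, tolerance = 1e-12)
})

test_that("identical cells receive identical networks", {
  vals <- matrix(rep(c(1, 2, 0, 3, 1.5), each = 2), 2, 5)
  expr <- expression_matrix(vals)
  kern <- cellgrn:::uniform_kernel(2)
  nbrs <- neighbor_sets(kern, 2, 2)
  cov <- cell_covariances(expr, kern, nbrs)
  fit <- infer_all_cells(expr, kern, nbrs, cov)
  expect_equal(fit$networks[1, , ], fit$networks[2, , ])
})

test_that("solver rejects malformed inputs", {
  expect_error(admm_solve(matrix(c(1, 2, 0, 1), 2), no_mask(2)), "symmetric")
  M_bad <- diag(2)
  expect_error(admm_solve(diag(2), M_bad), "diagonal")
  expect_error(solver_config(lam = -1), "lam")
  expect_error(solver_config(rho = 0), "rho")
})
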