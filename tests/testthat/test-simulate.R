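test_that("no rewiring events yields one static network", {
  truth <- simulate_grn_sequence(g = 6, n = 10, density = 0.2,
                                 n_rewire_events = 0, seed = 1)
  for (i in 2:10) {
    expect_equal(truth$thetas[i, , ], truth$thetas[1, , ])
    expect_equal(truth$supports[i, , ], truth$supports[1, , ])
  }
})

test_that("rewiring toggles exactly the chosen entries between anchors", {
  truth <- simulate_grn_sequence(g = 8, n = 2, density = 0.2,
                                 n_rewire_events = 1, toggle_fraction = 0.3,
                                 seed = 5)
  s1 <- truth$supports[1, , ]
  s2 <- truth$supports[2, , ]
  diffs <- sum(s1 != s2) / 2   # unordered pairs
  n_edges_start <- sum(s1[upper.tri(s1)])
  # exactly one toggle event of ~0.3 of the edges
  expect_gt(diffs, 0)
  expect_lte(diffs, max(1, round(0.3 * max(n_edges_start,
                                           sum(s2[upper.tri(s2)])))) + 1)
})

test_that("every simulated precision matrix is positive definite with the designed support", {
  truth <- simulate_grn_sequence(g = 10, n = 25, density = 0.15,
                                 n_rewire_events = 2, seed = 9)
  for (i in seq_len(25)) {
    th <- truth$thetas[i, , ]
    expect_equal(th, t(th))
    ev <- eigen(th, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
    off <- th; diag(off) <- 0
    expect_equal((abs(off) > 1e-8) * 1L, truth$supports[i, , ],
                 ignore_attr = TRUE)
  }
})

test_that("the generator is deterministic under a seed", {
  t1 <- simulate_grn_sequence(g = 6, n = 8, density = 0.2, seed = 77)
  t2 <- simulate_grn_sequence(g = 6, n = 8, density = 0.2, seed = 77)
  expect_identical(t1$thetas, t2$thetas)
  e1 <- sample_expression(t1, dropout_rate = 0.3, seed = 5)
  e2 <- sample_expression(t2, dropout_rate = 0.3, seed = 5)
  expect_identical(e1$values, e2$values)
  e3 <- sample_expression(t1, dropout_rate = 0.3, seed = 6)
  expect_false(identical(e1$values, e3$values))
})

test_that("latent Gaussian sampling reproduces the inverse precision", {
  # one static network, many draws, identity marginal: the sample
  # covariance must approach Theta^{-1}
  truth <- simulate_grn_sequence(g = 5, n = 5000, density = 0.2,
                                 n_rewire_events = 0, seed = 13)
  expr <- sample_expression(truth, dropout_rate = 0,
                            marginal = "gaussian-identity", seed = 14)
  emp <- cov(expr$values)
  expected <- solve(truth$thetas[1, , ])
  # each covariance entry within 4 Monte-Carlo standard errors
  se <- sqrt((tcrossprod(diag(expected)) + expected^2) / 5000)
  expect_true(all(abs(emp - expected) < 4 * se))
})

test_that("dropout produces the expected zero fraction", {
  truth <- simulate_grn_sequence(g = 10, n = 200, density = 0.1, seed = 21)
  expr <- sample_expression(truth, dropout_rate = 0.3,
                            marginal = "lognormal-quantile", seed = 22)
  # lognormal marginals have no native zeros, so all zeros are dropout
  zf <- mean(expr$values == 0)
  se <- sqrt(0.3 * 0.7 / 2000)
  expect_lt(abs(zf - 0.3), 4 * se)
  expect_true(all(expr$values >= 0))
})

test_that("exponential marginals are non-negative and copula-ordered", {
  truth <- simulate_grn_sequence(g = 6, n = 50, density = 0.2, seed = 31)
  expr <- sample_expression(truth, dropout_rate = 0,
                            marginal = "exponential-quantile", seed = 32)
  expect_true(all(expr$values >= 0))
})

test_that("prior corruption flips at the configured rate and stays symmetric", {
  truth <- simulate_grn_sequence(g = 15, n = 4, density = 0.2, seed = 41)
  # noise 0 -> prior equals true support off-diagonal
  pr0 <- corrupt_priors(truth, noise_level = 0, seed = 42)
  for (i in 1:4) {
    slice <- pr0$G_prior[i, , ]
    off <- slice; diag(off) <- 0
    expect_equal(off, truth$supports[i, , ] * 1, ignore_attr = TRUE)
    expect_equal(diag(slice), rep(1, 15))
  }
  # noise 0.1: flip count within binomial 99% bounds aggregated over seeds
  n_pairs <- 15 * 14 / 2
  flips <- 0
  trials <- 0
  for (s in 1:5) {
    pr <- corrupt_priors(truth, noise_level = 0.1, seed = s)
    for (i in 1:4) {
      off <- pr$G_prior[i, , ]; diag(off) <- 0
      flips <- flips + sum(off[upper.tri(off)] !=
                             truth$supports[i, , ][upper.tri(off)])
      trials <- trials + n_pairs
    }
    expect_true(all(pr$G_prior[1, , ] == t(pr$G_prior[1, , ])))
  }
  expected <- 0.1 * trials
  sd_bin <- sqrt(trials * 0.1 * 0.9)
  expect_lt(abs(flips - expected), 2.6 * sd_bin)
})

test_that("spatial layout produces coordinates and a smooth rewiring field", {
  truth <- simulate_grn_sequence(g = 6, n = 30, density = 0.2,
                                 layout = "spatial2d", seed = 51)
  expect_equal(dim(truth$coords), c(30L, 2L))
  expect_true(all(truth$pseudotime >= 0 & truth$pseudotime <= 1))
  # cells adjacent in the field have more similar networks than distant ones
  ord <- order(truth$pseudotime)
  d_adj <- mean(abs(truth$thetas[ord[1], , ] - truth$thetas[ord[2], , ]))
  d_far <- mean(abs(truth$thetas[ord[1], , ] - truth$thetas[ord[30], , ]))
  expect_lte(d_adj, d_far)
})

test_that("simulation files round-trip through the readers", {
  dir <- withr::local_tempdir()
  truth <- simulate_grn_sequence(g = 6, n = 10, density = 0.2, seed = 61)
  expr <- sample_expression(truth, dropout_rate = 0.2, seed = 62)
  priors <- corrupt_priors(truth, 0.05, seed = 63)
  files <- write_simulation(truth, expr, priors, file.path(dir, "sim"))
  back <- read_expression(files[["expression"]])
  expect_equal(back$values, expr$values, tolerance = 1e-12)
  truth_back <- read_grn_tensor(file.path(dir, "sim_truth"))
  expect_identical(truth_back$networks, truth$thetas)
})

test_that("degenerate generator parameters are rejected", {
  expect_error(simulate_grn_sequence(g = 3, n = 5), "g")
  expect_error(simulate_grn_sequence(g = 8, n = 5, density = 0.6), "density")
  expect_error(simulate_grn_sequence(g = 8, n = 5, density = 0.001),
               "zero edges")
  truth <- simulate_grn_sequence(g = 6, n = 4, seed = 1)
  expect_error(sample_expression(truth, dropout_rate = 1), "dropout")
  expect_error(corrupt_priors(truth, noise_level = 1), "noise")
})
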