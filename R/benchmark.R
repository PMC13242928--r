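#' Synthetic recovery benchmark
#'
#' Runs the full pipeline on a simulated dataset with known rewiring
#' ground truth and compares three predictors per cell: the cell-specific
#' fit, a single population-level network (one unweighted solve on the
#' classical rank covariance of all cells, applied to every cell), and the
#' prevalence (random-ranking) baseline, whose AUPRC equals the true edge
#' density.
#'
#' @param g,n,density,n_rewire_events,layout simulation parameters, see
#'   [simulate_grn_sequence()].
#' @param dropout_rate dropout probability for the sampled expression.
#' @param noise_level prior corruption rate, see [corrupt_priors()].
#' @param seed integer seed driving simulation, sampling and corruption.
#' @param lam,beta solver penalties for the cell-specific fit (the
#'   population solve uses the same `lam` and no mask).
#' @param k,n_objective,n_covariance,sigma kernel/neighbourhood parameters
#'   passed to [cellgrn()].
#' @param verbose log stages.
#' @return list with `cell_specific` and `population`
#'   ([evaluate_tensor()] reports), `prevalence` (mean true edge density
#'   over cells), and the `truth` object.
#' @export
benchmark_recovery <- function(g = 20, n = 200, density = 0.1,
                               n_rewire_events = 2,
                               layout = "trajectory",
                               dropout_rate = 0.2, noise_level = 0.01,
                               seed = 1, lam = 0.005, beta = 100,
                               k = 5, n_objective = NULL,
                               n_covariance = NULL, sigma = NULL,
                               verbose = FALSE) {
  seed <- as.integer(seed)
  truth <- simulate_grn_sequence(g = g, n = n, density = density,
                                 n_rewire_events = n_rewire_events,
                                 layout = layout, seed = seed)
  expr <- sample_expression(truth, dropout_rate = dropout_rate,
                            marginal = "lognormal-quantile", seed = seed + 1L)
  priors <- corrupt_priors(truth, noise_level = noise_level,
                           seed = seed + 2L)

  fit <- cellgrn(expr,
                 coords = if (layout == "spatial2d")
                   spatial_coordinates(truth$coords, truth$cell_ids)
                 else NULL,
                 prior = priors, k = k, sigma = sigma,
                 n_objective = n_objective, n_covariance = n_covariance,
                 lam = lam, beta = beta, verbose = verbose)
  eval_cs <- evaluate_tensor(fit$partial_correlation, truth)

  pop_G <- population_network(expr, lam = lam)
  pop_tensor <- grn_tensor(
    array(rep(pop_G, each = n), dim = c(n, g, g)),
    truth$gene_names, truth$cell_ids,
    kind = "partial_correlation", validate = FALSE)
  eval_pop <- evaluate_tensor(pop_tensor, truth)

  prevalence <- mean(apply(truth$supports, 1, function(s)
    mean(s[upper.tri(s)])))

  list(cell_specific = eval_cs, population = eval_pop,
       prevalence = prevalence, truth = truth, fit = fit)
}

#' Population-level network: one unweighted solve for all cells
#'
#' The baseline a cluster- or population-level method would produce:
#' classical zero-aware Kendall's tau over all cells with uniform weights,
#' sine-transformed, projected to the positive-definite cone, and solved
#' once with the same l1 penalty and no prior mask.
#'
#' @param expr a [expression_matrix()] object.
#' @param lam l1 penalty.
#' @param epsilon positive-definiteness floor.
#' @return g x g partial correlation matrix.
#' @export
population_network <- function(expr, lam = 0.005, epsilon = 1e-3) {
  stopifnot(inherits(expr, "cg_expression"))
  n <- nrow(expr$values)
  kern <- uniform_kernel(n)
  nbrs <- neighbor_sets(kern, n_objective = n, n_covariance = n)
  tau <- weighted_kendall_tau(expr, kern, nbrs, cell_j = 1L)
  S <- project_positive_definite(tau_to_covariance(tau), epsilon)
  res <- admm_solve(S, matrix(0, ncol(S), ncol(S)),
                    solver_config(lam = lam, beta = 0))
  partial_correlation(res$theta)
}
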