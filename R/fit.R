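#' Fit cell-specific gene regulatory networks
#'
#' The main entry point: estimates one undirected GRN per cell from a
#' cells-by-genes expression matrix. Each cell's network is the precision
#' matrix of a Gaussian copula graphical model, fitted to a kernel-weighted
#' neighbourhood of cells so networks change smoothly along the expression
#' manifold (default) or the spatial landscape (when `coords` is given).
#' The two-step pipeline is (i) kernel-weight construction and (ii)
#' per-cell penalized-likelihood solves: a rank-based (Kendall's tau)
#' covariance per cell, then an ADMM solve of the l1-penalized Gaussian
#' likelihood, optionally with a ridge penalty on edges forbidden by a
#' cell-specific prior network.
#'
#' @param expr a [expression_matrix()] object (or a bare cells x genes
#'   matrix, converted with default names).
#' @param coords optional [spatial_coordinates()]; when given, kernel
#'   weights are built from physical distances instead of the expression
#'   manifold.
#' @param prior optional `cg_prior` from [prior_from_atac()],
#'   [prior_from_tf_list()] or [prior_none()]; default no prior (the mask
#'   penalty is inert).
#' @param n_pcs,k,sigma kernel parameters, see [expression_kernel()].
#' @param n_objective,n_covariance neighbourhood sizes; default
#'   [default_neighborhood_size()] of n.
#' @param lam,beta,rho,max_iter,tol_primal,tol_dual,raw_scale solver
#'   parameters, see [solver_config()].
#' @param epsilon positive-definiteness floor for the covariance
#'   projection.
#' @param verbose log stage progress.
#' @return an object of class `cellgrn` with components `precision` and
#'   `partial_correlation` ([grn_tensor()]s), `kernel`, `neighbors`,
#'   `prior_mode`, `converged`, `Z` (sparse iterates, for edge support),
#'   and `call`.
#' @examples
#' truth <- simulate_grn_sequence(g = 8, n = 30, density = 0.15, seed = 1)
#' expr <- sample_expression(truth, dropout_rate = 0.1, seed = 1)
#' fit <- cellgrn(expr, k = 4, n_objective = 10, n_covariance = 10)
#' fit
#' head(coef(fit))
#' @export
cellgrn <- function(expr, coords = NULL, prior = NULL,
                    n_pcs = 20, k = 5, sigma = NULL,
                    n_objective = NULL, n_covariance = NULL,
                    lam = 0.005, beta = 100, rho = 1.0, max_iter = 1000,
                    tol_primal = 1e-5, tol_dual = 1e-5,
                    epsilon = 1e-3, raw_scale = FALSE, verbose = FALSE) {
  cl <- match.call()
  if (!inherits(expr, "cg_expression")) expr <- expression_matrix(expr)
  n <- nrow(expr$values)
  n_objective <- n_objective %||% default_neighborhood_size(n)
  n_covariance <- n_covariance %||% default_neighborhood_size(n)

  if (verbose) message("stage 1/4: kernel weights")
  kernel <- if (is.null(coords)) {
    expression_kernel(expr, n_pcs = n_pcs, k = k, sigma = sigma)
  } else {
    stopifnot(inherits(coords, "cg_coords"))
    if (nrow(coords$coords) != n)
      stopf("coordinates have %d rows but expression has %d cells",
            nrow(coords$coords), n)
    spatial_kernel(coords, k = k, sigma = sigma)
  }
  neighbors <- neighbor_sets(kernel, n_objective, n_covariance)

  if (verbose) message("stage 2/4: per-cell covariance estimation")
  cov <- cell_covariances(expr, kernel, neighbors, epsilon = epsilon,
                          verbose = verbose)

  if (verbose) message("stage 3/4: per-cell ADMM solves")
  config <- solver_config(lam = lam, beta = beta, rho = rho,
                          max_iter = max_iter, tol_primal = tol_primal,
                          tol_dual = tol_dual, raw_scale = raw_scale)
  if (is.null(prior)) prior <- prior_none(n, ncol(expr$values),
                                          expr$gene_names)
  theta_tensor <- infer_all_cells(expr, kernel, neighbors, cov,
                                  priors = prior, config = config,
                                  verbose = verbose)

  if (verbose) message("stage 4/4: partial correlations")
  G_tensor <- tensor_partial_correlation(theta_tensor)

  structure(list(precision = theta_tensor,
                 partial_correlation = G_tensor,
                 kernel = kernel, neighbors = neighbors,
                 prior_mode = prior$mode,
                 converged = attr(theta_tensor, "converged"),
                 Z = attr(theta_tensor, "Z"),
                 gene_names = expr$gene_names,
                 cell_ids = expr$cell_ids,
                 config = config, call = cl),
            class = "cellgrn")
}

#' @export
print.cellgrn <- function(x, ...) {
  n <- length(x$cell_ids); g <- length(x$gene_names)
  cat(sprintf("Cell-specific GRN fit: %d cells, %d genes\n", n, g))
  cat(sprintf("  prior: %s; kernel bandwidth %.4g; kNN k = %d\n",
              x$prior_mode, x$kernel$bandwidth, x$kernel$knn_k))
  cat(sprintf("  lambda = %g, beta = %g; %d/%d cells converged\n",
              x$config$lam, x$config$beta, sum(x$converged), n))
  mean_edges <- mean(apply(x$Z, 1, function(s) {
    diag(s) <- 0; sum(abs(s[upper.tri(s)]) > 1e-8)
  }))
  cat(sprintf("  mean edges per cell (nonzero sparse iterate): %.1f of %d pairs\n",
              mean_edges, g * (g - 1) / 2))
  invisible(x)
}

#' @export
summary.cellgrn <- function(object, regulators = character(),
                            threshold = NULL, ...) {
  dyn <- summarize_dynamics(object$partial_correlation,
                            regulators = regulators, threshold = threshold)
  out <- list(dynamics = dyn,
              n_cells = length(object$cell_ids),
              n_genes = length(object$gene_names),
              converged = object$converged,
              prior_mode = object$prior_mode)
  class(out) <- "summary.cellgrn"
  out
}

#' @export
print.summary.cellgrn <- function(x, ...) {
  cat(sprintf("Cell-specific GRN fit: %d cells, %d genes (prior: %s)\n",
              x$n_cells, x$n_genes, x$prior_mode))
  ranked <- rank_genes_and_edges(x$dynamics, top_k = min(5L, x$n_genes))
  cat("Top genes by mean total edge weight:\n")
  print(ranked$genes_by_mean, row.names = FALSE)
  cat("Top genes by rewiring (variance of total edge weight):\n")
  print(ranked$genes_by_variance, row.names = FALSE)
  cat("Most variable edges across cells:\n")
  print(ranked$edges_by_variance, row.names = FALSE)
  invisible(x)
}

#' Edge table of a fitted model
#'
#' Long-format partial-correlation edge weights: one row per cell per
#' unordered gene pair (`gene_a` lexicographically before `gene_b`).
#'
#' @param object a [cellgrn()] fit.
#' @param ... unused.
#' @return data frame with columns `cell_id`, `gene_a`, `gene_b`,
#'   `weight`.
#' @export
coef.cellgrn <- function(object, ...) {
  tensor <- object$partial_correlation
  g <- length(tensor$gene_names)
  pairs <- upper_pairs(g)
  a <- tensor$gene_names[pairs[, 1]]
  b <- tensor$gene_names[pairs[, 2]]
  swap <- a > b
  ga <- ifelse(swap, b, a); gb <- ifelse(swap, a, b)
  do.call(rbind, lapply(seq_along(tensor$cell_ids), function(i) {
    data.frame(cell_id = tensor$cell_ids[i], gene_a = ga, gene_b = gb,
               weight = tensor$networks[i, , ][pairs],
               stringsAsFactors = FALSE)
  }))
}

#' Plot one cell's inferred network
#'
#' Heatmap of the absolute partial-correlation matrix for a chosen cell.
#'
#' @param x a [cellgrn()] fit.
#' @param cell cell index or id (default 1).
#' @param ... passed to [graphics::image()].
#' @export
plot.cellgrn <- function(x, cell = 1, ...) {
  if (is.character(cell)) cell <- match(cell, x$cell_ids)
  if (is.na(cell) || cell < 1 || cell > length(x$cell_ids))
    stopf("unknown cell")
  G <- abs(x$partial_correlation$networks[cell, , ])
  g <- nrow(G)
  graphics::image(seq_len(g), seq_len(g), t(G[g:1, ]),
                  axes = FALSE, xlab = "", ylab = "",
                  main = sprintf("|partial correlation|, cell %s",
                                 x$cell_ids[cell]), ...)
  graphics::axis(1, at = seq_len(g), labels = x$gene_names, las = 2,
                 cex.axis = 0.7)
  graphics::axis(2, at = seq_len(g), labels = rev(x$gene_names), las = 2,
                 cex.axis = 0.7)
  invisible(x)
}
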