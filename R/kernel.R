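#' Kernel weights from expression data
#'
#' Approximates distance along the expression manifold and converts it to
#' a Gaussian kernel weight per cell pair. The pipeline: (1) center genes
#' and project cells onto `n_pcs` principal components; (2) pairwise
#' Euclidean distances in PC space; (3) symmetric k-nearest-neighbour graph
#' (an edge is kept when either endpoint lists the other) with Euclidean
#' edge weights; (4) all-pairs shortest-path (geodesic) distances `D`;
#' (5) `K = exp(-D^2 / (2 sigma^2))`.
#'
#' The bandwidth `sigma` controls how fast a neighbour's influence decays
#' with geodesic distance: a small bandwidth lets networks change quickly
#' between nearby cells, a large one enforces slow change. If the k-NN
#' graph is disconnected, components are bridged by the shortest
#' inter-component Euclidean edges (logged) so every distance is finite.
#'
#' @param expr a [expression_matrix()] object.
#' @param n_pcs number of principal components (default 20, capped at
#'   `min(n, g) - 1`).
#' @param k neighbours for the k-NN graph (default 5).
#' @param sigma Gaussian bandwidth; default `median(D)/2` computed from the
#'   geodesic distances.
#' @return an object of class `cg_kernel` with fields `K`, `geodesic_D`,
#'   `bandwidth`, `knn_k`.
#' @export
expression_kernel <- function(expr, n_pcs = 20, k = 5, sigma = NULL) {
  stopifnot(inherits(expr, "cg_expression"))
  n <- nrow(expr$values)
  g <- ncol(expr$values)
  k <- check_count(k, "k")
  if (k >= n) stopf("k (%d) must be smaller than the number of cells (%d)", k, n)
  n_pcs <- check_count(n_pcs, "n_pcs")
  n_pcs <- min(n_pcs, min(n, g) - 1L)
  if (n_pcs < 1L) stopf("too few cells/genes for PCA")
  pcs <- prcomp(expr$values, center = TRUE, scale. = FALSE,
                rank. = n_pcs)$x
  kernel_from_points(pcs, k = k, sigma = sigma)
}

#' Kernel weights from spatial coordinates
#'
#' Identical pipeline to [expression_kernel()] with the PCA step skipped:
#' distances are taken directly in the physical coordinate space, for data
#' where networks are assumed to change smoothly across the tissue rather
#' than along the expression manifold.
#'
#' @param coords a [spatial_coordinates()] object.
#' @inheritParams expression_kernel
#' @return an object of class `cg_kernel`.
#' @export
spatial_kernel <- function(coords, k = 5, sigma = NULL) {
  stopifnot(inherits(coords, "cg_coords"))
  n <- nrow(coords$coords)
  k <- check_count(k, "k")
  if (k >= n) stopf("k (%d) must be smaller than the number of cells (%d)", k, n)
  kernel_from_points(coords$coords, k = k, sigma = sigma)
}

# Shared tail of both kernel constructors: kNN graph -> geodesic D -> K.
kernel_from_points <- function(points, k, sigma) {
  n <- nrow(points)
  D_euc <- as.matrix(dist(points))
  D_geo <- geodesic_distances(D_euc, k)
  kernel_from_distances(D_geo, sigma, knn_k = k)
}

# Symmetric-union kNN graph, minimally bridged if disconnected, then
# all-pairs shortest paths.
geodesic_distances <- function(D_euc, k) {
  n <- nrow(D_euc)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    nb <- order(D_euc[i, ], seq_len(n))  # self first (distance 0)
    nb <- setdiff(nb, i)[seq_len(k)]
    adj[i, nb] <- TRUE
  }
  adj <- adj | t(adj)   # union kNN: edge if either endpoint lists the other
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(gr)
  while (comp$no > 1L) {
    # add globally shortest Euclidean edge between any two components
    best <- c(NA_integer_, NA_integer_); best_d <- Inf
    for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
      if (comp$membership[i] != comp$membership[j] && D_euc[i, j] < best_d) {
        best <- c(i, j); best_d <- D_euc[i, j]
      }
    }
    message(sprintf("kNN graph disconnected; bridging cells %d and %d (distance %.4g)",
                    best[1], best[2], best_d))
    adj[best[1], best[2]] <- adj[best[2], best[1]] <- TRUE
    gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(gr)
  }
  w_list <- D_euc[cbind(igraph::as_edgelist(gr, names = FALSE)[, 1],
                        igraph::as_edgelist(gr, names = FALSE)[, 2])]
  D_geo <- igraph::distances(gr, weights = w_list, algorithm = "dijkstra")
  symmetrize(unname(D_geo))
}

# Gaussian kernel on a finished distance matrix. Exposed internally so that
# expression and spatial modes provably share every step after distance
# construction.
kernel_from_distances <- function(D, sigma = NULL, knn_k = NA_integer_) {
  if (!is_symmetric_tol(D, 1e-8) || any(diag(D) != 0))
    stopf("distance matrix must be symmetric with zero diagonal")
  if (is.null(sigma)) {
    off <- D[upper.tri(D)]
    sigma <- median(off) / 2
    if (!is.finite(sigma) || sigma <= 0) sigma <- 1
  }
  sigma <- check_positive(sigma, "sigma")
  K <- exp(-D^2 / (2 * sigma^2))
  structure(list(K = K, geodesic_D = D, bandwidth = sigma, knn_k = knn_k),
            class = "cg_kernel")
}

#' Neighbour sets for the objective and the covariance estimator
#'
#' Two distinct neighbourhoods are used downstream: the objective
#' neighbourhood `N_i` (whose cells' likelihood terms are averaged when
#' inferring cell i's network) and the covariance neighbourhood `N_j`
#' (whose cells enter the weighted rank-correlation estimate for cell j).
#' Both are the cells at smallest geodesic distance, self included, with
#' ties broken by ascending cell index for determinism.
#'
#' @param kernel a `cg_kernel` object.
#' @param n_objective size of each `N_i` (>= 1).
#' @param n_covariance size of each `N_j` (>= 2; rank correlation needs
#'   pairs).
#' @return an object of class `cg_neighbors` with integer-matrix fields
#'   `objective_neighbors` (n x n_objective) and `covariance_neighbors`
#'   (n x n_covariance); row i lists the members of the corresponding set.
#' @export
neighbor_sets <- function(kernel, n_objective, n_covariance) {
  stopifnot(inherits(kernel, "cg_kernel"))
  n <- nrow(kernel$K)
  n_objective <- check_count(n_objective, "n_objective")
  n_covariance <- check_count(n_covariance, "n_covariance", min = 2L)
  if (n_objective > n) stopf("n_objective (%d) exceeds n (%d)", n_objective, n)
  if (n_covariance > n) stopf("n_covariance (%d) exceeds n (%d)", n_covariance, n)
  D <- kernel$geodesic_D
  obj <- matrix(NA_integer_, n, n_objective)
  cov <- matrix(NA_integer_, n, n_covariance)
  for (i in seq_len(n)) {
    ord <- order(D[i, ], seq_len(n))  # distance, then index: deterministic
    obj[i, ] <- ord[seq_len(n_objective)]
    cov[i, ] <- ord[seq_len(n_covariance)]
  }
  structure(list(objective_neighbors = obj, covariance_neighbors = cov,
                 n_objective = n_objective, n_covariance = n_covariance),
            class = "cg_neighbors")
}

#' Default neighbourhood size
#'
#' `max(15, ceiling(0.1 n))`, capped at `n`: large enough for a stable
#' rank-correlation estimate at small n, scaling with the data at large n.
#'
#' @param n number of cells.
#' @return integer neighbourhood size.
#' @export
default_neighborhood_size <- function(n) {
  as.integer(min(n, max(15, ceiling(0.1 * n))))
}
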