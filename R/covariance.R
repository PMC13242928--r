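#' Neighbourhood-weighted, zero-aware Kendall's tau for one cell
#'
#' Rank correlation between every gene pair, estimated over the cells in
#' cell j's covariance neighbourhood `N_j`. Each ordered pair of distinct
#' cells (k, k') contributes the concordance sign
#' `sign((X[k,m]-X[k',m]) * (X[k,n]-X[k',n]))`, weighted by
#' `w = b[k,m] b[k',m] b[k,n] b[k',n] K[k,k']` where `b[k,m] = 0` iff the
#' measurement is zero (dropout-aware: zero measurements carry no rank
#' information) and `K` is the cell-cell kernel weight. The sum is divided
#' by the unweighted ordered-pair count `|Nj| (|Nj|-1)`, so zero-rich or
#' low-weight neighbourhoods are shrunk toward zero correlation. Tied
#' nonzero values contribute sign 0.
#'
#' @param expr a [expression_matrix()] object.
#' @param kernel a `cg_kernel` object.
#' @param neighbors a [neighbor_sets()] object.
#' @param cell_j cell index whose neighbourhood is used.
#' @param normalize_weights divide by the summed weights per entry instead
#'   of the fixed ordered-pair count (off by default; the fixed denominator
#'   is the estimator's definition, the alternative removes its shrinkage).
#' @return g x g matrix of tau values in `[-1, 1]`. The diagonal is
#'   computed like any other entry but is overwritten by the unit diagonal
#'   when converted to a covariance.
#' @export
weighted_kendall_tau <- function(expr, kernel, neighbors, cell_j,
                                 normalize_weights = FALSE) {
  stopifnot(inherits(expr, "cg_expression"),
            inherits(kernel, "cg_kernel"),
            inherits(neighbors, "cg_neighbors"))
  nj <- neighbors$covariance_neighbors[cell_j, ]
  N <- length(nj)
  if (N < 2L) stopf("covariance neighbourhood must contain at least 2 cells")
  X <- expr$values[nj, , drop = FALSE]
  B <- (X != 0) * 1
  g <- ncol(X)

  pairs <- which(upper.tri(matrix(FALSE, N, N)), arr.ind = TRUE)
  k1 <- pairs[, 1]; k2 <- pairs[, 2]
  # u[p, m] = b*b*sign(X[k1,m] - X[k2,m]); tau = 2 * sum_p K_p u_p u_p^T / denom
  U <- sign(X[k1, , drop = FALSE] - X[k2, , drop = FALSE]) *
    (B[k1, , drop = FALSE] * B[k2, , drop = FALSE])
  Kp <- kernel$K[cbind(nj[k1], nj[k2])]
  num <- 2 * crossprod(U * sqrt(Kp))          # sum over ordered pairs
  if (normalize_weights) {
    W <- 2 * crossprod((B[k1, , drop = FALSE] * B[k2, , drop = FALSE]) *
                         sqrt(Kp))
    tau <- ifelse(W > 0, num / W, 0)
  } else {
    tau <- num / (N * (N - 1))
  }
  unname(tau)
}

#' Sine transform from Kendall's tau to a nonparanormal covariance
#'
#' For a Gaussian copula, the latent Pearson correlation relates to
#' Kendall's tau by `rho = sin(pi/2 * tau)`; applying this entrywise to the
#' rank-based tau matrix gives a covariance estimate that is invariant to
#' the unknown monotone marginal transforms. The diagonal is pinned to
#' exactly 1.
#'
#' @param tau g x g matrix of tau values.
#' @return g x g covariance estimate (not yet positive definite).
#' @export
tau_to_covariance <- function(tau) {
  stopifnot(is.matrix(tau), nrow(tau) == ncol(tau))
  if (any(abs(tau) > 1 + 1e-12))
    stopf("tau entries outside [-1, 1] (max |tau| = %g)", max(abs(tau)))
  S <- sin(pi / 2 * pmin(pmax(tau, -1), 1))
  diag(S) <- 1
  S
}

#' Project a symmetric matrix to the positive-definite cone
#'
#' Eigendecomposes and replaces every non-positive eigenvalue with a small
#' floor `epsilon`, leaving the positive eigenspace untouched. Input that
#' is already positive definite is returned unchanged.
#'
#' @param S symmetric matrix.
#' @param epsilon replacement for non-positive eigenvalues (default 1e-3).
#' @return positive-definite matrix of the same dimension.
#' @export
project_positive_definite <- function(S, epsilon = 1e-3) {
  epsilon <- check_positive(epsilon, "epsilon")
  if (!is_symmetric_tol(S, 1e-8))
    stopf("matrix is not symmetric (max asymmetry %g)", max(abs(S - t(S))))
  S <- symmetrize(S)
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) > 0) return(S)
  vals <- ifelse(e$values <= 0, epsilon, e$values)
  out <- e$vectors %*% (vals * t(e$vectors))
  symmetrize(out)
}

#' Per-cell nonparanormal covariance matrices
#'
#' Applies [weighted_kendall_tau()], [tau_to_covariance()] and
#' [project_positive_definite()] for every cell. Cells are independent, so
#' the result does not depend on evaluation order.
#'
#' @inheritParams weighted_kendall_tau
#' @param epsilon positive-definiteness floor passed to
#'   [project_positive_definite()].
#' @param keep_tau retain the raw tau array in the result.
#' @param verbose log progress every 50 cells.
#' @return an object of class `cg_covariance` with fields `Sigma`
#'   (`n x g x g`), `epsilon`, and optionally `tau`.
#' @export
cell_covariances <- function(expr, kernel, neighbors, epsilon = 1e-3,
                             normalize_weights = FALSE, keep_tau = FALSE,
                             verbose = FALSE) {
  n <- nrow(expr$values)
  g <- ncol(expr$values)
  Sigma <- array(NA_real_, dim = c(n, g, g))
  tau_arr <- if (keep_tau) array(NA_real_, dim = c(n, g, g)) else NULL
  for (j in seq_len(n)) {
    tau <- weighted_kendall_tau(expr, kernel, neighbors, j,
                                normalize_weights = normalize_weights)
    if (keep_tau) tau_arr[j, , ] <- tau
    Sigma[j, , ] <- project_positive_definite(tau_to_covariance(tau),
                                              epsilon = epsilon)
    if (verbose && j %% 50 == 0)
      message(sprintf("covariance: %d/%d cells", j, n))
  }
  structure(list(Sigma = Sigma, epsilon = epsilon, tau = tau_arr),
            class = "cg_covariance")
}
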