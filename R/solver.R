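#' Solver configuration
#'
#' Collects the hyperparameters of the per-cell penalized-likelihood solve.
#'
#' @param lam l1 sparsity weight (>= 0). Interpreted on the normalized
#'   objective `-logdet(Theta) + tr(S_bar Theta) + lam ||Theta||_1 + ...`
#'   unless `raw_scale = TRUE` (see [infer_all_cells()]).
#' @param beta mask (prior) ridge weight (>= 0).
#' @param rho ADMM penalty parameter (> 0).
#' @param max_iter iteration cap.
#' @param tol_primal,tol_dual convergence tolerances, each scaled by g.
#' @param init `"identity"` or `"inverse_sigma"` initialization of Theta.
#' @param adapt_rho enable residual-balancing rho adaptation (factor 2,
#'   bounds `[1e-3, 1e3]`).
#' @param raw_scale solve the verbatim neighbourhood-mass-scaled objective:
#'   lam and beta are divided by `|Ni| * Wi / 2` per cell, so their
#'   effective strength varies with neighbourhood mass.
#' @return a list of class `cg_solver_config`.
#' @export
solver_config <- function(lam = 0.005, beta = 100, rho = 1.0, max_iter = 1000,
                          tol_primal = 1e-5, tol_dual = 1e-5,
                          init = c("identity", "inverse_sigma"),
                          adapt_rho = FALSE, raw_scale = FALSE) {
  init <- match.arg(init)
  if (lam < 0) stopf("lam must be >= 0")
  if (beta < 0) stopf("beta must be >= 0")
  rho <- check_positive(rho, "rho")
  max_iter <- check_count(max_iter, "max_iter")
  tol_primal <- check_positive(tol_primal, "tol_primal")
  tol_dual <- check_positive(tol_dual, "tol_dual")
  structure(list(lam = lam, beta = beta, rho = rho, max_iter = max_iter,
                 tol_primal = tol_primal, tol_dual = tol_dual, init = init,
                 adapt_rho = adapt_rho, raw_scale = raw_scale),
            class = "cg_solver_config")
}

#' Assemble the weighted data term for one cell
#'
#' The kernel-weighted sum of neighbourhood likelihood terms collapses to a
#' single weighted-average covariance: with `Wi = sum_{j in Ni} Kij`, the
#' objective for cell i is proportional to
#' `-logdet(Theta) + tr(S_bar_i Theta)` with
#' `S_bar_i = sum_{j in Ni} Kij Sigma_j / Wi`, plus the penalties rescaled
#' by `2 / (|Ni| Wi)`. The optimum is unchanged by this normalization.
#'
#' @param kernel a `cg_kernel` object.
#' @param neighbors a [neighbor_sets()] object.
#' @param cov a [cell_covariances()] object.
#' @param cell_i index of the cell whose network is being inferred.
#' @return list with `S_bar` (g x g), `W` (total kernel weight), and
#'   `n_objective`.
#' @export
assemble_cell_data <- function(kernel, neighbors, cov, cell_i) {
  stopifnot(inherits(cov, "cg_covariance"))
  ni <- neighbors$objective_neighbors[cell_i, ]
  w <- kernel$K[cell_i, ni]
  W <- sum(w)
  g <- dim(cov$Sigma)[2]
  S_bar <- matrix(0, g, g)
  for (t in seq_along(ni)) S_bar <- S_bar + w[t] * cov$Sigma[ni[t], , ]
  list(S_bar = symmetrize(S_bar / W), W = W, n_objective = length(ni))
}

#' ADMM solve of the masked, l1-penalized Gaussian likelihood
#'
#' Minimizes `-logdet(Theta) + tr(S Theta) + lam ||Theta||_1 +
#' beta ||M o Theta||_F^2` over positive-definite Theta by splitting
#' `Theta = Z`. The Theta-update has a closed form via eigendecomposition
#' of `rho (Z - U) - S`: eigenvalue `d` maps to
#' `(d + sqrt(d^2 + 4 rho)) / (2 rho)`, which is strictly positive, so
#' every Theta iterate is symmetric positive definite. The Z-update is the
#' exact proximal map of the combined penalty: soft-thresholding at
#' `lam / rho`, with masked entries additionally shrunk by
#' `rho / (rho + 2 beta)`. Convergence when
#' `||Theta - Z||_F <= tol_primal * g` and
#' `rho ||Z - Z_prev||_F <= tol_dual * g`.
#'
#' @param S symmetric data matrix (weighted covariance).
#' @param mask_M binary mask of penalized entries, zero diagonal.
#' @param config a [solver_config()]; `lam`/`beta` are used as given (any
#'   neighbourhood rescaling happens in [infer_all_cells()]).
#' @param track_pd record the smallest eigenvalue of every Theta iterate
#'   (slow; for verification).
#' @return list of class `cg_solve_result`: `theta` (the symmetrized
#'   average `(Theta + Z)/2`, the value matrix), `Z` (the exactly sparse
#'   iterate, read for edge support), `iterations`, `primal_residual`,
#'   `dual_residual`, `converged`, and optionally `theta_min_eigen`.
#' @export
admm_solve <- function(S, mask_M, config = solver_config(),
                       track_pd = FALSE) {
  g <- nrow(S)
  if (!is_symmetric_tol(S, 1e-8)) stopf("data matrix S must be symmetric")
  stopifnot(nrow(mask_M) == g, ncol(mask_M) == g)
  if (any(diag(mask_M) != 0)) stopf("mask diagonal must be zero")
  S <- symmetrize(S)
  lam <- config$lam; beta <- config$beta; rho <- config$rho

  Theta <- if (config$init == "inverse_sigma") {
    solve(project_positive_definite(S, 1e-3))
  } else diag(g)
  Z <- Theta
  U <- matrix(0, g, g)
  masked <- mask_M != 0
  min_eigs <- if (track_pd) numeric(config$max_iter) else NULL
  converged <- FALSE
  iter <- 0L
  r_primal <- r_dual <- Inf

  for (iter in seq_len(config$max_iter)) {
    # Theta-update: closed form keeping Theta in the PD cone
    A <- symmetrize(rho * (Z - U) - S)
    e <- eigen(A, symmetric = TRUE)
    d <- (e$values + sqrt(e$values^2 + 4 * rho)) / (2 * rho)
    Theta <- e$vectors %*% (d * t(e$vectors))
    Theta <- symmetrize(Theta)
    if (track_pd) min_eigs[iter] <- min(d)

    # Z-update: prox of lam*||Z||_1 + beta*||M o Z||_F^2
    Z_prev <- Z
    V <- Theta + U
    Z <- soft_threshold(V, lam / rho)
    if (beta > 0 && any(masked))
      Z[masked] <- Z[masked] * rho / (rho + 2 * beta)

    U <- U + Theta - Z

    r_primal <- sqrt(sum((Theta - Z)^2))
    r_dual <- rho * sqrt(sum((Z - Z_prev)^2))
    if (!all(is.finite(Theta)) || !all(is.finite(Z)))
      stopf("non-finite ADMM iterate at iteration %d (rho=%g, lam=%g, beta=%g)",
            iter, rho, lam, beta)
    if (r_primal <= config$tol_primal * g && r_dual <= config$tol_dual * g) {
      converged <- TRUE
      break
    }
    if (config$adapt_rho) {
      if (r_primal > 10 * r_dual && rho < 1e3) {
        rho <- rho * 2; U <- U / 2
      } else if (r_dual > 10 * r_primal && rho > 1e-3) {
        rho <- rho / 2; U <- U * 2
      }
    }
  }

  theta <- symmetrize((Theta + Z) / 2)
  # the averaged iterate can graze the cone boundary before full
  # convergence; fall back to the guaranteed-PD Theta iterate if it does
  if (min(eigen(theta, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    theta <- Theta
  structure(list(theta = theta, Z = Z, iterations = iter,
                 primal_residual = r_primal, dual_residual = r_dual,
                 converged = converged,
                 theta_min_eigen = if (track_pd) min_eigs[seq_len(iter)] else NULL),
            class = "cg_solve_result")
}

#' Infer precision matrices for all cells
#'
#' Runs [assemble_cell_data()] and [admm_solve()] per cell. Cells are
#' solved independently, so results do not depend on execution order; a
#' cell that fails to converge within `max_iter` produces a warning and is
#' flagged, not an error.
#'
#' @param expr a [expression_matrix()] object (used for dimensions/names).
#' @param kernel a `cg_kernel` object.
#' @param neighbors a [neighbor_sets()] object.
#' @param cov a [cell_covariances()] object.
#' @param priors a `cg_prior` object (use [prior_none()] for no prior).
#' @param config a [solver_config()].
#' @param verbose log every 50 cells.
#' @return a [grn_tensor()] of kind `"precision"`, with attributes
#'   `converged` (logical per cell) and `Z` (the sparse iterates,
#'   `n x g x g`, read for edge support).
#' @export
infer_all_cells <- function(expr, kernel, neighbors, cov, priors = NULL,
                            config = solver_config(), verbose = FALSE) {
  n <- nrow(expr$values)
  g <- ncol(expr$values)
  if (is.null(priors)) priors <- prior_none(n, g, expr$gene_names)
  stopifnot(dim(priors$M)[1] == n, dim(priors$M)[2] == g)
  thetas <- array(NA_real_, dim = c(n, g, g))
  Zs <- array(NA_real_, dim = c(n, g, g))
  conv <- logical(n)
  for (i in seq_len(n)) {
    dat <- assemble_cell_data(kernel, neighbors, cov, i)
    cfg <- config
    if (config$raw_scale) {
      scale <- 2 / (dat$n_objective * dat$W)
      cfg$lam <- config$lam * scale
      cfg$beta <- config$beta * scale
    }
    M_i <- priors$M[i, , ]
    diag(M_i) <- 0
    res <- admm_solve(dat$S_bar, M_i, cfg)
    thetas[i, , ] <- res$theta
    Zs[i, , ] <- res$Z
    conv[i] <- res$converged
    if (!res$converged)
      warnf("cell %d: ADMM did not converge in %d iterations (primal %.2g, dual %.2g)",
            i, cfg$max_iter, res$primal_residual, res$dual_residual)
    if (verbose && i %% 50 == 0)
      message(sprintf("solver: %d/%d cells", i, n))
  }
  out <- grn_tensor(thetas, expr$gene_names, expr$cell_ids,
                    kind = "precision", validate = FALSE)
  attr(out, "converged") <- conv
  attr(out, "Z") <- Zs
  out
}
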