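# Independent oracle implementations used to verify the package's fast
# paths. These deliberately use naive algorithms (explicit loops, exhaustive
# enumeration) and share no code with the implementation.

# Quadruple-loop weighted, zero-annotated Kendall's tau: direct transcription
# of the estimator's definition over ordered cell pairs.
oracle_kendall_tau <- function(X, K, nj) {
  g <- ncol(X)
  N <- length(nj)
  tau <- matrix(0, g, g)
  for (m in seq_len(g)) for (n in seq_len(g)) {
    acc <- 0
    for (k in nj) for (kp in nj) {
      if (k == kp) next
      b <- (X[k, m] != 0) * (X[kp, m] != 0) * (X[k, n] != 0) * (X[kp, n] != 0)
      if (b == 0) next
      acc <- acc + K[k, kp] *
        sign((X[k, m] - X[kp, m]) * (X[k, n] - X[kp, n]))
    }
    tau[m, n] <- acc / (N * (N - 1))
  }
  tau
}

# Classical blockwise coordinate-descent graphical lasso (diagonal
# penalized), solving min -logdet(Theta) + tr(S Theta) + lam ||Theta||_1.
oracle_glasso <- function(S, lam, tol = 1e-10, max_sweeps = 2000) {
  g <- nrow(S)
  W <- S + lam * diag(g)
  B <- matrix(0, g - 1, g)
  soft <- function(x, t) sign(x) * max(abs(x) - t, 0)
  for (sweep in seq_len(max_sweeps)) {
    W_old <- W
    for (j in seq_len(g)) {
      idx <- setdiff(seq_len(g), j)
      W11 <- W[idx, idx, drop = FALSE]
      s12 <- S[idx, j]
      beta <- B[, j]
      repeat {
        beta_old <- beta
        for (l in seq_len(g - 1)) {
          r <- s12[l] - sum(W11[l, -l] * beta[-l])
          beta[l] <- soft(r, lam) / W11[l, l]
        }
        if (max(abs(beta - beta_old)) < tol) break
      }
      B[, j] <- beta
      w12 <- W11 %*% beta
      W[idx, j] <- w12
      W[j, idx] <- w12
    }
    if (max(abs(W - W_old)) < tol) break
  }
  Theta <- matrix(0, g, g)
  for (j in seq_len(g)) {
    idx <- setdiff(seq_len(g), j)
    theta_jj <- 1 / (W[j, j] - sum(W[idx, j] * B[, j]))
    Theta[j, j] <- theta_jj
    Theta[idx, j] <- -B[, j] * theta_jj
  }
  (Theta + t(Theta)) / 2
}

# Exhaustive threshold-sweep area under the precision-recall curve.
oracle_auprc <- function(scores, labels) {
  stopifnot(sum(labels) > 0)
  thresholds <- sort(unique(scores), decreasing = TRUE)
  recall <- precision <- numeric(length(thresholds))
  P <- sum(labels)
  for (t in seq_along(thresholds)) {
    sel <- scores >= thresholds[t]
    recall[t] <- sum(labels[sel]) / P
    precision[t] <- sum(labels[sel]) / sum(sel)
  }
  sum(diff(c(0, recall)) * precision)
}

# Floyd-Warshall all-pairs shortest paths on a weighted adjacency matrix
# (Inf where no edge).
oracle_shortest_paths <- function(Wadj) {
  n <- nrow(Wadj)
  D <- Wadj
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# Random symmetric positive-definite matrix with unit-scale eigenvalues.
random_pd <- function(g, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(g * g), g, g)
  S <- crossprod(A) / g + 0.1 * diag(g)
  (S + t(S)) / 2
}

# Random correlation-like PD matrix (unit diagonal), the scale the
# estimated covariances live on.
random_corr_pd <- function(g, seed = NULL) {
  S <- random_pd(g, seed)
  d <- 1 / sqrt(diag(S))
  S <- S * tcrossprod(d)
  (S + t(S)) / 2
}

# Tiny deterministic expression fixture with some exact zeros.
toy_expression <- function(n = 6, g = 4, seed = 42, zero_frac = 0.2) {
  set.seed(seed)
  vals <- matrix(round(rexp(n * g), 3), n, g)
  vals[matrix(runif(n * g) < zero_frac, n, g)] <- 0
  expression_matrix(vals)
}
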