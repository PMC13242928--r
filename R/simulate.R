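#' Simulate a smoothly rewiring sequence of ground-truth networks
#'
#' Generates one sparse positive-definite precision matrix per cell along
#' a 1-D trajectory or a 2-D spatial landscape, rewiring smoothly: a
#' random sparse support is drawn at the start, a random subset of edges
#' is toggled at each of `n_rewire_events` evenly spaced anchor points,
#' and off-diagonal weights interpolate linearly between anchors
#' (so toggled edges fade in or out rather than jumping). Positive
#' definiteness is enforced by strict diagonal dominance: each diagonal
#' entry is the row's absolute off-diagonal sum plus 0.1, which preserves
#' the designed support exactly.
#'
#' @param g gene count (>= 4).
#' @param n cell count.
#' @param density fraction of the `g(g-1)/2` gene pairs carrying an edge
#'   (0 < density < 0.5).
#' @param n_rewire_events number of rewiring anchor points (0 = one static
#'   network).
#' @param layout `"trajectory"` (cells evenly spaced on a 1-D pseudotime)
#'   or `"spatial2d"` (cells uniform in the unit square; rewiring follows
#'   the smooth field x + y).
#' @param toggle_fraction fraction of current edges toggled per rewiring
#'   event (at least one edge).
#' @param weight_range magnitude range for edge weights; signs are random.
#' @param seed integer seed; the generator is deterministic given it.
#' @return an object of class `cg_sim_truth` with fields `thetas`
#'   (`n x g x g`), `supports` (binary, diagonal 0), `pseudotime`, `coords`
#'   (spatial2d only), `gene_names`, `cell_ids`, `layout`, `seed`.
#' @export
simulate_grn_sequence <- function(g, n, density = 0.1, n_rewire_events = 2,
                                  layout = c("trajectory", "spatial2d"),
                                  toggle_fraction = 0.5,
                                  weight_range = c(0.2, 0.8),
                                  seed = 1) {
  layout <- match.arg(layout)
  g <- check_count(g, "g", min = 4L)
  n <- check_count(n, "n", min = 2L)
  if (density <= 0 || density >= 0.5)
    stopf("density must be in (0, 0.5)")
  n_rewire_events <- check_count(n_rewire_events, "n_rewire_events", min = 0L)
  set.seed(as.integer(seed))

  pairs <- upper_pairs(g)
  n_pairs <- nrow(pairs)
  n_edges <- round(density * n_pairs)
  if (n_edges < 1) stopf("density %g yields zero edges for g = %d", density, g)

  rand_weight <- function(m)
    sample(c(-1, 1), m, replace = TRUE) *
      runif(m, weight_range[1], weight_range[2])

  # anchor weight vectors over the pair index
  n_anchors <- n_rewire_events + 1L
  W_anchor <- matrix(0, n_anchors, n_pairs)
  support <- logical(n_pairs)
  support[sample.int(n_pairs, n_edges)] <- TRUE
  W_anchor[1, support] <- rand_weight(sum(support))
  if (n_anchors > 1) {
    for (r in 2:n_anchors) {
      n_toggle <- max(1L, round(toggle_fraction * sum(support)))
      toggled <- sample.int(n_pairs, n_toggle)
      support[toggled] <- !support[toggled]
      w <- W_anchor[r - 1, ]
      w[toggled] <- ifelse(support[toggled], rand_weight(n_toggle), 0)
      # redraw nothing else: untouched edges keep their weights
      W_anchor[r, ] <- w * support
    }
  }

  if (layout == "spatial2d") {
    coords <- cbind(runif(n), runif(n))
    t_pos <- (coords[, 1] + coords[, 2]) / 2   # smooth linear field
    t_pos <- (t_pos - min(t_pos)) / max(t_pos - min(t_pos))
  } else {
    coords <- NULL
    t_pos <- if (n == 1) 0 else (seq_len(n) - 1) / (n - 1)
  }

  anchor_t <- if (n_anchors == 1) 0 else (seq_len(n_anchors) - 1) / (n_anchors - 1)
  thetas <- array(0, dim = c(n, g, g))
  supports <- array(0L, dim = c(n, g, g))
  gene_names <- paste0("g", seq_len(g))
  cell_ids <- paste0("cell_", seq_len(n))
  for (i in seq_len(n)) {
    if (n_anchors == 1) {
      w <- W_anchor[1, ]
    } else {
      seg <- findInterval(t_pos[i], anchor_t, rightmost.closed = TRUE)
      seg <- min(seg, n_anchors - 1L)
      f <- (t_pos[i] - anchor_t[seg]) / (anchor_t[seg + 1] - anchor_t[seg])
      w <- (1 - f) * W_anchor[seg, ] + f * W_anchor[seg + 1, ]
    }
    Theta <- matrix(0, g, g)
    Theta[pairs] <- w
    Theta <- Theta + t(Theta)
    diag(Theta) <- rowSums(abs(Theta)) + 0.1
    thetas[i, , ] <- Theta
    supp <- matrix(0L, g, g)
    supp[pairs] <- as.integer(abs(w) > 1e-8)
    supports[i, , ] <- supp + t(supp)
  }
  structure(list(thetas = thetas, supports = supports,
                 pseudotime = t_pos, coords = coords,
                 gene_names = gene_names, cell_ids = cell_ids,
                 layout = layout, seed = as.integer(seed)),
            class = "cg_sim_truth")
}

#' Sample copula-transformed expression from ground-truth networks
#'
#' For each cell, draws a latent Gaussian vector with covariance
#' `Theta_i^{-1}`, maps every coordinate through the standard-normal CDF
#' and then the chosen marginal quantile function (a Gaussian copula, so
#' the latent network structure survives the non-Gaussian marginals), and
#' finally zeroes each entry independently with probability
#' `dropout_rate` to emulate dropout.
#'
#' @param truth a [simulate_grn_sequence()] result.
#' @param dropout_rate excess-zero probability in `[0, 1)`.
#' @param marginal `"lognormal-quantile"` (meanlog 0, sdlog 1),
#'   `"exponential-quantile"` (rate 1), or `"gaussian-identity"` (no
#'   transform; latent Gaussian returned as-is, for calibration checks —
#'   this is the one configuration allowed to produce negative values).
#' @param seed integer seed.
#' @return a [expression_matrix()] object.
#' @export
sample_expression <- function(truth, dropout_rate = 0.2,
                              marginal = c("lognormal-quantile",
                                           "exponential-quantile",
                                           "gaussian-identity"),
                              seed = 1) {
  stopifnot(inherits(truth, "cg_sim_truth"))
  marginal <- match.arg(marginal)
  if (dropout_rate < 0 || dropout_rate >= 1)
    stopf("dropout_rate must be in [0, 1)")
  set.seed(as.integer(seed))
  n <- dim(truth$thetas)[1]
  g <- dim(truth$thetas)[2]
  X <- matrix(0, n, g)
  for (i in seq_len(n)) {
    R <- chol(truth$thetas[i, , ])
    z <- backsolve(R, rnorm(g))          # cov(z) = Theta^{-1}
    if (marginal == "gaussian-identity") {
      X[i, ] <- z
    } else {
      sd_i <- sqrt(diag(chol2inv(R)))
      u <- pnorm(z / sd_i)
      X[i, ] <- switch(marginal,
        "lognormal-quantile" = qlnorm(u),
        "exponential-quantile" = qexp(u))
    }
  }
  if (dropout_rate > 0) {
    drop <- matrix(runif(n * g) < dropout_rate, n, g)
    X[drop] <- 0
  }
  expression_matrix(X, truth$gene_names, truth$cell_ids,
                    check_nonneg = marginal != "gaussian-identity")
}

#' Corrupt true supports into noisy prior networks
#'
#' Starts from each cell's true edge support and flips every unordered
#' off-diagonal prior entry independently with probability `noise_level`,
#' mirroring the flip so the prior stays symmetric; the diagonal stays 1.
#' This emulates errors in the cross-modality link between chromatin
#' regions and genes.
#'
#' @param truth a [simulate_grn_sequence()] result.
#' @param noise_level flip probability in `[0, 1)`.
#' @param seed integer seed.
#' @return a `cg_prior` object (mode `"atac"`).
#' @export
corrupt_priors <- function(truth, noise_level = 0.01, seed = 1) {
  stopifnot(inherits(truth, "cg_sim_truth"))
  if (noise_level < 0 || noise_level >= 1)
    stopf("noise_level must be in [0, 1)")
  set.seed(as.integer(seed))
  n <- dim(truth$supports)[1]
  g <- dim(truth$supports)[2]
  pairs <- upper_pairs(g)
  G <- array(0, dim = c(n, g, g))
  for (i in seq_len(n)) {
    w <- truth$supports[i, , ][pairs]
    flip <- runif(nrow(pairs)) < noise_level
    w[flip] <- 1 - w[flip]
    slice <- matrix(0, g, g)
    slice[pairs] <- w
    slice <- slice + t(slice)
    diag(slice) <- 1
    G[i, , ] <- slice
  }
  new_prior(G, mode = "atac", gene_names = truth$gene_names)
}

#' Write a simulated benchmark to disk in the package's input formats
#'
#' Writes expression (CSV), coordinates or pseudotime (CSV), the
#' ground-truth tensor (archive + edge table via [write_grn_tensor()]),
#' and prior adjacencies (archive), so a command-line round trip through
#' the reading functions can be tested end to end.
#'
#' @param truth a [simulate_grn_sequence()] result.
#' @param expr a [sample_expression()] result.
#' @param priors optional `cg_prior`.
#' @param out_prefix path prefix.
#' @return invisibly, the files written.
#' @export
write_simulation <- function(truth, expr, priors = NULL, out_prefix) {
  expr_path <- paste0(out_prefix, "_expression.csv")
  df <- data.frame(cell_id = expr$cell_ids, expr$values,
                   check.names = FALSE)
  write.table(df, expr_path, sep = ",", quote = FALSE, row.names = FALSE)
  pos_path <- paste0(out_prefix, "_positions.csv")
  if (truth$layout == "spatial2d") {
    write.table(data.frame(cell_id = truth$cell_ids,
                           x = truth$coords[, 1], y = truth$coords[, 2]),
                pos_path, sep = ",", quote = FALSE, row.names = FALSE)
  } else {
    write.table(data.frame(cell_id = truth$cell_ids,
                           pseudotime = truth$pseudotime),
                pos_path, sep = ",", quote = FALSE, row.names = FALSE)
  }
  truth_tensor <- grn_tensor(truth$thetas, truth$gene_names, truth$cell_ids,
                             kind = "precision", validate = FALSE)
  truth_files <- write_grn_tensor(truth_tensor, paste0(out_prefix, "_truth"))
  files <- c(expression = expr_path, positions = pos_path, truth_files)
  if (!is.null(priors)) {
    prior_path <- paste0(out_prefix, "_priors.rds")
    saveRDS(priors, prior_path)
    files <- c(files, priors = prior_path)
  }
  invisible(files)
}
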