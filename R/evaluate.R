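#' Area under the precision-recall curve for one network
#'
#' Ranks the unordered off-diagonal gene pairs by absolute predicted
#' weight (the diagonal is excluded, the sign is ignored for detection)
#' and sweeps all thresholds, grouping tied scores into a single step.
#' The area is the precision-weighted recall increment sum
#' `sum_k (R_k - R_{k-1}) P_k`, so a constant predictor scores exactly the
#' edge density (prevalence).
#'
#' @param pred symmetric g x g weight matrix.
#' @param truth_support symmetric binary g x g matrix of true edges.
#' @return AUPRC in `[0, 1]`.
#' @export
auprc <- function(pred, truth_support) {
  sc <- pair_scores(pred, truth_support)
  if (sum(sc$label) == 0)
    stopf("truth has zero positive edges; AUPRC undefined")
  ord <- order(-sc$score)
  score <- sc$score[ord]
  label <- sc$label[ord]
  # group tied scores into single PR steps
  grp <- cumsum(!duplicated(score))
  tp_g <- tapply(label, grp, sum)
  n_g <- tapply(label, grp, length)
  tp <- cumsum(tp_g)
  pos_seen <- cumsum(n_g)
  P <- sum(label)
  recall <- tp / P
  precision <- tp / pos_seen
  sum(diff(c(0, recall)) * precision)
}

#' Early precision of a predicted network
#'
#' Precision among the top-k unordered pairs ranked by absolute predicted
#' weight; by default k equals the number of true edges, so a perfect
#' predictor scores 1. Ties at the k-th rank break by lexicographic pair
#' order, making the score deterministic.
#'
#' @inheritParams auprc
#' @param k number of top pairs (default: number of true edges).
#' @return early precision in `[0, 1]`.
#' @export
early_precision <- function(pred, truth_support, k = NULL) {
  sc <- pair_scores(pred, truth_support)
  if (is.null(k)) k <- sum(sc$label)
  k <- check_count(k, "k")
  if (k > length(sc$score))
    stopf("k (%d) exceeds the number of unordered pairs (%d)",
          k, length(sc$score))
  ord <- order(-sc$score, sc$gene_a, sc$gene_b)
  mean(sc$label[ord][seq_len(k)])
}

# Shared flattening: unordered off-diagonal pairs with |weight| scores,
# binary labels, and deterministic pair names.
pair_scores <- function(pred, truth_support) {
  stopifnot(is.matrix(pred), is.matrix(truth_support),
            all(dim(pred) == dim(truth_support)))
  if (!is_symmetric_tol(pred, 1e-8) || !is_symmetric_tol(truth_support, 1e-8))
    stopf("prediction and truth must be symmetric")
  g <- nrow(pred)
  pairs <- upper_pairs(g)
  list(score = abs(pred[pairs]),
       label = as.integer(truth_support[pairs] != 0),
       gene_a = pairs[, 1], gene_b = pairs[, 2])
}

#' Evaluate a predicted tensor against simulation ground truth
#'
#' Scores every cell's predicted network against that cell's true support
#' with [auprc()] and [early_precision()], and reports the per-cell
#' vectors with their means and standard deviations. Gene names must match
#' in order: a permuted prediction is an error, never silently realigned.
#'
#' @param pred_tensor a [grn_tensor()] (any kind; ranking uses absolute
#'   values).
#' @param truth a [simulate_grn_sequence()] result, or a
#'   [grn_tensor()]/array of true supports.
#' @return an object of class `cg_evaluation` with fields
#'   `per_cell_auprc`, `per_cell_early_precision`, `mean_auprc`,
#'   `sd_auprc`, `mean_early_precision`, `sd_early_precision`, `settings`.
#' @export
evaluate_tensor <- function(pred_tensor, truth) {
  stopifnot(inherits(pred_tensor, "cg_grn_tensor"))
  if (inherits(truth, "cg_sim_truth")) {
    supports <- truth$supports
    truth_genes <- truth$gene_names
  } else if (inherits(truth, "cg_grn_tensor")) {
    supports <- (truth$networks != 0) * 1L
    for (i in seq_len(dim(supports)[1])) diag(supports[i, , ]) <- 0L
    truth_genes <- truth$gene_names
  } else {
    stopf("truth must be a cg_sim_truth or cg_grn_tensor")
  }
  dp <- dim(pred_tensor$networks)
  dt <- dim(supports)
  if (!all(dp == dt))
    stopf("dimension mismatch: prediction %s vs truth %s",
          paste(dp, collapse = "x"), paste(dt, collapse = "x"))
  if (!identical(as.character(pred_tensor$gene_names),
                 as.character(truth_genes)))
    stopf("gene names differ between prediction and truth; refusing to realign silently")
  n <- dp[1]
  au <- ep <- numeric(n)
  for (i in seq_len(n)) {
    au[i] <- auprc(pred_tensor$networks[i, , ], supports[i, , ])
    ep[i] <- early_precision(pred_tensor$networks[i, , ], supports[i, , ])
  }
  structure(list(per_cell_auprc = au, per_cell_early_precision = ep,
                 mean_auprc = mean(au), sd_auprc = stats::sd(au),
                 mean_early_precision = mean(ep),
                 sd_early_precision = stats::sd(ep),
                 settings = list(diagonal_excluded = TRUE,
                                 absolute_values = TRUE)),
            class = "cg_evaluation")
}

#' Write an evaluation report
#'
#' @param report a [evaluate_tensor()] result.
#' @param out_prefix path prefix; writes `<prefix>_per_cell.tsv` and
#'   `<prefix>_summary.json`.
#' @param cell_ids optional cell identifiers for the per-cell table.
#' @return invisibly, the file paths.
#' @export
write_evaluation <- function(report, out_prefix, cell_ids = NULL) {
  stopifnot(inherits(report, "cg_evaluation"))
  n <- length(report$per_cell_auprc)
  cell_ids <- cell_ids %||% paste0("cell_", seq_len(n))
  tsv <- paste0(out_prefix, "_per_cell.tsv")
  js <- paste0(out_prefix, "_summary.json")
  write.table(data.frame(cell_id = cell_ids,
                         auprc = report$per_cell_auprc,
                         early_precision = report$per_cell_early_precision),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(mean_auprc = report$mean_auprc,
                            sd_auprc = report$sd_auprc,
                            mean_early_precision = report$mean_early_precision,
                            sd_early_precision = report$sd_early_precision),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(per_cell = tsv, summary = js))
}
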