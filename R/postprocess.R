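#' Partial correlation matrix from a precision matrix
#'
#' Normalizes precision entries to edge weights:
#' `G[m, n] = -Theta[m, n] / sqrt(Theta[m, m] * Theta[n, n])` off the
#' diagonal. A larger absolute value means a stronger conditional
#' (direct) association between the two genes. The diagonal is reported
#' as 0: self-partial-correlation is not an edge.
#'
#' @param theta symmetric precision matrix with strictly positive diagonal.
#' @return g x g partial correlation matrix, zero diagonal.
#' @export
partial_correlation <- function(theta) {
  stopifnot(is.matrix(theta), nrow(theta) == ncol(theta))
  if (!is_symmetric_tol(theta, 1e-8)) stopf("precision matrix must be symmetric")
  d <- diag(theta)
  if (any(d <= 0))
    stopf("precision diagonal has non-positive entries (violates positive definiteness)")
  s <- 1 / sqrt(d)
  G <- -theta * tcrossprod(s)
  diag(G) <- 0
  symmetrize(G)
}

#' Convert a precision tensor to partial correlations
#'
#' @param tensor a [grn_tensor()] of kind `"precision"`.
#' @return a [grn_tensor()] of kind `"partial_correlation"`.
#' @export
tensor_partial_correlation <- function(tensor) {
  stopifnot(inherits(tensor, "cg_grn_tensor"))
  if (tensor$kind != "precision")
    stopf("expected a precision tensor, got kind '%s'", tensor$kind)
  out <- tensor$networks
  for (i in seq_len(dim(out)[1]))
    out[i, , ] <- partial_correlation(tensor$networks[i, , ])
  grn_tensor(out, tensor$gene_names, tensor$cell_ids,
             kind = "partial_correlation", validate = FALSE)
}

#' Summaries of network dynamics across cells
#'
#' For each gene, the total absolute edge weight incident to it in each
#' cell's network; its mean across cells measures overall regulatory
#' activity, its variance measures how much the gene rewires across the
#' cell population. Per-edge variance across cells identifies the
#' interactions that rewire the most. For selected regulator genes, the
#' number of targets whose edge weight exceeds a threshold is reported per
#' cell. Variances are population variances (denominator n), since every
#' cell in the dataset is observed.
#'
#' @param tensor a [grn_tensor()] of kind `"partial_correlation"`.
#' @param regulators genes for which thresholded target counts are
#'   computed (default: none).
#' @param threshold edge-weight threshold for target counting; default the
#'   90th percentile of `|G|` over all off-diagonal entries of the tensor.
#' @return an object of class `cg_dynamics` with fields
#'   `gene_total_weight` (n x g), `gene_mean`, `gene_var` (length g),
#'   `edge_var` (g x g), `target_counts` (n x length(regulators)),
#'   `threshold`.
#' @export
summarize_dynamics <- function(tensor, regulators = character(),
                               threshold = NULL) {
  stopifnot(inherits(tensor, "cg_grn_tensor"))
  if (tensor$kind != "partial_correlation")
    stopf("expected a partial_correlation tensor, got kind '%s'", tensor$kind)
  unknown <- setdiff(regulators, tensor$gene_names)
  if (length(unknown))
    stopf("unknown regulator gene(s): %s", paste(unknown, collapse = ", "))
  n <- dim(tensor$networks)[1]
  g <- dim(tensor$networks)[2]
  pairs <- upper_pairs(g)
  if (is.null(threshold)) {
    all_off <- abs(apply(tensor$networks, 1, function(s) s[pairs]))
    threshold <- as.numeric(stats::quantile(all_off, 0.9))
  }
  gene_total <- matrix(0, n, g, dimnames = list(tensor$cell_ids,
                                                tensor$gene_names))
  edge_mean <- matrix(0, g, g)
  edge_sq <- matrix(0, g, g)
  reg_idx <- match(regulators, tensor$gene_names)
  target_counts <- matrix(0L, n, length(regulators),
                          dimnames = list(tensor$cell_ids, regulators))
  for (i in seq_len(n)) {
    Gm <- tensor$networks[i, , ]
    diag(Gm) <- 0
    gene_total[i, ] <- rowSums(abs(Gm))
    edge_mean <- edge_mean + Gm
    edge_sq <- edge_sq + Gm^2
    if (length(reg_idx))
      target_counts[i, ] <- vapply(reg_idx, function(f)
        sum(abs(Gm[f, -f]) > threshold), integer(1))
  }
  edge_mean <- edge_mean / n
  edge_var <- edge_sq / n - edge_mean^2
  edge_var <- pmax(symmetrize(edge_var), 0)
  diag(edge_var) <- 0
  gene_mean <- colMeans(gene_total)
  gene_var <- colMeans(gene_total^2) - gene_mean^2
  structure(list(gene_total_weight = gene_total,
                 gene_mean = gene_mean,
                 gene_var = pmax(gene_var, 0),
                 edge_var = edge_var,
                 target_counts = target_counts,
                 threshold = threshold,
                 gene_names = tensor$gene_names),
            class = "cg_dynamics")
}

#' Rank genes and edges by dynamics
#'
#' Genes are ranked separately by mean total edge weight (overall
#' regulatory activity) and by its variance across cells (rewiring
#' activity); edges by across-cell weight variance. Ties break
#' lexicographically by gene name for determinism.
#'
#' @param summary a [summarize_dynamics()] result.
#' @param top_k how many genes/edges to return.
#' @return list with data frames `genes_by_mean`, `genes_by_variance`
#'   (columns `gene`, `value`) and `edges_by_variance` (columns `gene_a`,
#'   `gene_b`, `variance`).
#' @export
rank_genes_and_edges <- function(summary, top_k) {
  stopifnot(inherits(summary, "cg_dynamics"))
  g <- length(summary$gene_names)
  top_k <- check_count(top_k, "top_k")
  if (top_k > g) stopf("top_k (%d) exceeds gene count (%d)", top_k, g)
  genes <- summary$gene_names
  ord_mean <- order(-summary$gene_mean, genes)
  ord_var <- order(-summary$gene_var, genes)
  pairs <- upper_pairs(g)
  a <- genes[pairs[, 1]]; b <- genes[pairs[, 2]]
  swap <- a > b
  ga <- ifelse(swap, b, a); gb <- ifelse(swap, a, b)
  ev <- summary$edge_var[pairs]
  if (top_k > length(ev)) stopf("top_k (%d) exceeds edge count (%d)",
                                top_k, length(ev))
  ord_edge <- order(-ev, ga, gb)
  list(
    genes_by_mean = data.frame(gene = genes[ord_mean][seq_len(top_k)],
                               value = summary$gene_mean[ord_mean][seq_len(top_k)],
                               row.names = NULL),
    genes_by_variance = data.frame(gene = genes[ord_var][seq_len(top_k)],
                                   value = summary$gene_var[ord_var][seq_len(top_k)],
                                   row.names = NULL),
    edges_by_variance = data.frame(gene_a = ga[ord_edge][seq_len(top_k)],
                                   gene_b = gb[ord_edge][seq_len(top_k)],
                                   variance = ev[ord_edge][seq_len(top_k)],
                                   row.names = NULL)
  )
}

#' Write dynamics summary tables
#'
#' @param summary a [summarize_dynamics()] result.
#' @param out_prefix output path prefix; writes `<prefix>_genes.tsv`
#'   (name, mean, variance) and `<prefix>_edges.tsv`
#'   (gene_a, gene_b, variance).
#' @return invisibly, the file paths.
#' @export
write_dynamics <- function(summary, out_prefix) {
  stopifnot(inherits(summary, "cg_dynamics"))
  genes_path <- paste0(out_prefix, "_genes.tsv")
  edges_path <- paste0(out_prefix, "_edges.tsv")
  write.table(data.frame(gene = summary$gene_names,
                         mean = summary$gene_mean,
                         variance = summary$gene_var),
              genes_path, sep = "\t", quote = FALSE, row.names = FALSE)
  g <- length(summary$gene_names)
  pairs <- upper_pairs(g)
  write.table(data.frame(gene_a = summary$gene_names[pairs[, 1]],
                         gene_b = summary$gene_names[pairs[, 2]],
                         variance = summary$edge_var[pairs]),
              edges_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(genes = genes_path, edges = edges_path))
}
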