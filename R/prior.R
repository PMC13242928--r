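#' Cell-specific prior networks from chromatin accessibility
#'
#' Builds one binary prior adjacency per cell from paired accessibility
#' data. For each cell, a region contributes only if it is accessible in
#' that cell. A region is linked to a target gene when it overlaps the
#' window extending `window_bp` bases upstream of the gene's TSS
#' (strand-aware: `[TSS - window_bp, TSS]` on the + strand, mirrored on the
#' - strand; any base overlap counts, half-open arithmetic). A region is
#' linked to a TF when the region carries that TF's motif. A prior edge
#' between TF f and gene t exists in a cell when some region accessible in
#' that cell links both. Diagonals are fixed to 1 so the derived mask never
#' penalizes precision diagonals. All connections route through TF motifs:
#' target-target edges are never created.
#'
#' @param acc a [accessibility_inputs()] object.
#' @param expr_genes gene names of the expression matrix (ordering of the
#'   adjacency).
#' @param window_bp upstream window in bases (default 50000).
#' @return an object of class `cg_prior` with fields `G_prior`
#'   (`n x g x g` binary array), `M` (`1 - G_prior`), `mode = "atac"`.
#' @export
prior_from_atac <- function(acc, expr_genes, window_bp = 50000) {
  stopifnot(inherits(acc, "cg_accessibility"))
  window_bp <- check_count(window_bp, "window_bp")
  if (is.null(acc$tss_table) || nrow(acc$tss_table) == 0)
    stopf("accessibility prior requires a TSS table")
  expr_genes <- as.character(expr_genes)
  g <- length(expr_genes)
  n <- nrow(acc$region_matrix)
  n_regions <- nrow(acc$region_coords)

  # region -> target gene links via the strand-aware upstream window
  tss <- acc$tss_table[acc$tss_table$gene %in% expr_genes, , drop = FALSE]
  region_targets <- vector("list", n_regions)   # gene indices per region
  for (ti in seq_len(nrow(tss))) {
    gene_idx <- match(tss$gene[ti], expr_genes)
    on_chrom <- which(acc$region_coords$chrom == tss$chrom[ti])
    if (!length(on_chrom)) next
    if (tss$strand[ti] == "+") {
      win_start <- tss$tss[ti] - window_bp
      win_end <- tss$tss[ti] + 1L          # include the TSS base, half-open
    } else {
      win_start <- tss$tss[ti]
      win_end <- tss$tss[ti] + window_bp + 1L
    }
    hit <- on_chrom[acc$region_coords$start[on_chrom] < win_end &
                    win_start < acc$region_coords$end[on_chrom]]
    for (r in hit) region_targets[[r]] <- c(region_targets[[r]], gene_idx)
  }

  # region -> TF links via motif hits
  region_tfs <- vector("list", n_regions)
  if (nrow(acc$motif_hits)) {
    tf_idx <- match(acc$motif_hits$tf_name, expr_genes)
    keep <- !is.na(tf_idx)
    for (h in which(keep)) {
      r <- acc$motif_hits$region_index[h]
      region_tfs[[r]] <- c(region_tfs[[r]], tf_idx[h])
    }
  }

  G <- array(0, dim = c(n, g, g))
  for (i in seq_len(n)) {
    slice <- matrix(0, g, g)
    active <- which(acc$region_matrix[i, ] == 1)
    for (r in active) {
      tfs <- unique(region_tfs[[r]])
      tgts <- unique(region_targets[[r]])
      if (length(tfs) && length(tgts)) {
        slice[tfs, tgts] <- 1
        slice[tgts, tfs] <- 1
      }
    }
    diag(slice) <- 1
    G[i, , ] <- slice
  }
  new_prior(G, mode = "atac", gene_names = expr_genes)
}

#' Prior network from a transcription-factor list
#'
#' When accessibility data is unavailable, prior knowledge reduces to
#' which genes are TFs. Interactions in a GRN are mainly TF-TF or
#' TF-target, so the prior forbids exactly the target-target pairs: entry
#' (a, b) is 0 iff both a and b are non-TF targets, 1 otherwise. The same
#' adjacency is broadcast to every cell.
#'
#' @param tf_names genes considered TFs; names absent from `expr_genes`
#'   are dropped with a warning.
#' @param expr_genes gene names of the expression matrix.
#' @param n_cells number of cells to broadcast to.
#' @return an object of class `cg_prior` with `mode = "tf"`.
#' @export
prior_from_tf_list <- function(tf_names, expr_genes, n_cells) {
  expr_genes <- as.character(expr_genes)
  n_cells <- check_count(n_cells, "n_cells")
  tf_names <- as.character(tf_names)
  missing <- setdiff(tf_names, expr_genes)
  if (length(missing)) {
    warnf("dropping %d TF name(s) absent from expression genes: %s",
          length(missing), paste(missing, collapse = ", "))
    tf_names <- intersect(tf_names, expr_genes)
  }
  if (!length(tf_names))
    stopf("empty TF list: the prior would forbid every off-diagonal edge")
  g <- length(expr_genes)
  is_tf <- expr_genes %in% tf_names
  slice <- matrix(0, g, g)
  slice[is_tf, ] <- 1
  slice[, is_tf] <- 1
  diag(slice) <- 1
  G <- array(rep(slice, each = n_cells), dim = c(n_cells, g, g))
  new_prior(G, mode = "tf", gene_names = expr_genes)
}

#' Inert prior (no prior information)
#'
#' All-ones adjacencies: the mask is all zeros, so the mask penalty term
#' vanishes and only the l1 penalty shapes the networks.
#'
#' @param n_cells,g dimensions.
#' @param gene_names optional gene names.
#' @return an object of class `cg_prior` with `mode = "none"`.
#' @export
prior_none <- function(n_cells, g, gene_names = NULL) {
  G <- array(1, dim = c(n_cells, g, g))
  new_prior(G, mode = "none", gene_names = gene_names)
}

new_prior <- function(G, mode, gene_names = NULL) {
  stopifnot(is.array(G), length(dim(G)) == 3L, dim(G)[2] == dim(G)[3])
  if (!all(G %in% c(0, 1))) stopf("prior adjacencies must be binary")
  structure(list(G_prior = G, M = 1 - G, mode = mode,
                 gene_names = gene_names),
            class = "cg_prior")
}
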