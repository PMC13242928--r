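#' Construct an expression matrix object
#'
#' Wraps a cells-by-genes numeric matrix with gene and cell identifiers and
#' validates the invariants the downstream model relies on: no missing
#' values, no duplicated names, and (by default) no negative entries —
#' expression is expected to be library-normalized, log-transformed data
#' where zeros are meaningful measurements, not missingness.
#'
#' @param values numeric matrix, cells in rows, genes in columns.
#' @param gene_names character vector of unique gene names (defaults to
#'   column names of `values`).
#' @param cell_ids character vector of unique cell identifiers (defaults to
#'   row names, or `cell_1..cell_n`).
#' @param check_nonneg require non-negative entries (`TRUE` for real
#'   expression data; the Gaussian-marginal synthetic configuration is the
#'   one legitimate exception).
#' @return an object of class `cg_expression` with fields `values`,
#'   `gene_names`, `cell_ids`.
#' @export
expression_matrix <- function(values, gene_names = NULL, cell_ids = NULL,
                              check_nonneg = TRUE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  gene_names <- gene_names %||% colnames(values) %||%
    paste0("gene_", seq_len(ncol(values)))
  cell_ids <- cell_ids %||% rownames(values) %||%
    paste0("cell_", seq_len(nrow(values)))
  gene_names <- as.character(gene_names)
  cell_ids <- as.character(cell_ids)
  if (length(gene_names) != ncol(values))
    stopf("expected %d gene names, got %d", ncol(values), length(gene_names))
  if (length(cell_ids) != nrow(values))
    stopf("expected %d cell ids, got %d", nrow(values), length(cell_ids))
  if (anyDuplicated(gene_names))
    stopf("duplicate gene names: %s",
          paste(unique(gene_names[duplicated(gene_names)]), collapse = ", "))
  if (anyDuplicated(cell_ids))
    stopf("duplicate cell ids: %s",
          paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", "))
  if (anyNA(values) || any(!is.finite(values)))
    stopf("expression matrix contains missing or non-finite values")
  if (check_nonneg && any(values < 0))
    stopf("expression matrix contains negative entries")
  dimnames(values) <- list(cell_ids, gene_names)
  structure(list(values = values, gene_names = gene_names,
                 cell_ids = cell_ids),
            class = "cg_expression")
}

#' Read an expression matrix from CSV, TSV or MatrixMarket triplet files
#'
#' CSV/TSV files carry a header row of gene names; an optional first column
#' of cell ids is detected when its entries are non-numeric. MatrixMarket
#' input expects sibling files `<stem>_genes.txt` and `<stem>_cells.txt`
#' (one name per line) next to the `.mtx` file, or explicit paths.
#'
#' Orientation is cells-as-rows by default and never silently transposed:
#' set `cells_as_rows = FALSE` if your file stores genes in rows.
#'
#' @param path path to the matrix file.
#' @param format_hint one of `"csv"`, `"tsv"`, `"mtx-triplet"`; default
#'   guesses from the file extension.
#' @param cells_as_rows logical; declare the orientation of the file.
#' @param genes_path,cells_path name files for MatrixMarket input.
#' @return a [expression_matrix()] object.
#' @export
read_expression <- function(path, format_hint = c("auto", "csv", "tsv", "mtx-triplet"),
                            cells_as_rows = TRUE,
                            genes_path = NULL, cells_path = NULL) {
  format_hint <- match.arg(format_hint)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format_hint == "auto") {
    ext <- tolower(tools::file_ext(path))
    format_hint <- switch(ext,
      csv = "csv", tsv = "tsv", txt = "tsv", mtx = "mtx-triplet",
      stopf("cannot guess format of '%s'; pass format_hint", path))
  }
  if (format_hint == "mtx-triplet") {
    stem <- sub("\\.mtx$", "", path)
    genes_path <- genes_path %||% paste0(stem, "_genes.txt")
    cells_path <- cells_path %||% paste0(stem, "_cells.txt")
    if (!file.exists(genes_path)) stopf("gene name file not found: %s", genes_path)
    if (!file.exists(cells_path)) stopf("cell id file not found: %s", cells_path)
    m <- as.matrix(Matrix::readMM(path))
    genes <- readLines(genes_path)
    cells <- readLines(cells_path)
    if (!cells_as_rows) m <- t(m)
    if (nrow(m) != length(cells))
      stopf("matrix has %d rows but %d cell ids", nrow(m), length(cells))
    if (ncol(m) != length(genes))
      stopf("matrix has %d columns but %d gene names", ncol(m), length(genes))
    return(expression_matrix(m, gene_names = genes, cell_ids = cells))
  }
  sep <- if (format_hint == "csv") "," else "\t"
  df <- tryCatch(
    read.table(path, header = TRUE, sep = sep, check.names = FALSE,
               stringsAsFactors = FALSE),
    error = function(e) stopf("failed to parse %s: %s", path, conditionMessage(e)))
  # leading id column: either an explicit non-numeric first column, or
  # read.table's automatic row names when the header is one field short
  row_ids <- NULL
  if (ncol(df) >= 2 && !is.numeric(df[[1]])) {
    row_ids <- as.character(df[[1]])
    df <- df[, -1, drop = FALSE]
  } else if (!identical(attr(df, "row.names"), seq_len(nrow(df)))) {
    row_ids <- rownames(df)
  }
  bad <- which(!vapply(df, is.numeric, logical(1)))
  if (length(bad))
    stopf("non-numeric values in column(s): %s",
          paste(names(df)[bad], collapse = ", "))
  m <- as.matrix(df)
  header <- colnames(df)
  if (!cells_as_rows) {
    m <- t(m)
    expression_matrix(m, gene_names = row_ids %||%
                        paste0("gene_", seq_len(ncol(m))),
                      cell_ids = header)
  } else {
    expression_matrix(m, gene_names = header, cell_ids = row_ids)
  }
}

#' Library-size normalization and log1p transform
#'
#' Optional preprocessing for raw counts: scales each cell to the median
#' library size and applies `log1p`. Never applied implicitly; the fitting
#' functions take the expression matrix as given.
#'
#' @param expr a [expression_matrix()] object of non-negative counts.
#' @param scale_to target library size (default: median of the cell sums).
#' @return a preprocessed `cg_expression`.
#' @export
preprocess_expression <- function(expr, scale_to = NULL) {
  stopifnot(inherits(expr, "cg_expression"))
  libs <- rowSums(expr$values)
  if (any(libs == 0)) stopf("cells with zero total counts: %s",
                            paste(expr$cell_ids[libs == 0], collapse = ", "))
  scale_to <- scale_to %||% median(libs)
  v <- log1p(expr$values / libs * scale_to)
  message(sprintf("preprocess: library-size normalized to %.1f and log1p-transformed", scale_to))
  expression_matrix(v, expr$gene_names, expr$cell_ids)
}

#' Construct spatial coordinates
#'
#' @param coords numeric matrix of cell positions, 2 or 3 columns, same
#'   physical units per axis.
#' @param cell_ids cell identifiers aligned with the expression matrix.
#' @return an object of class `cg_coords`.
#' @export
spatial_coordinates <- function(coords, cell_ids = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (!ncol(coords) %in% c(2L, 3L))
    stopf("coordinates must have 2 or 3 columns, got %d", ncol(coords))
  if (anyNA(coords) || any(!is.finite(coords)))
    stopf("coordinates contain missing or non-finite values")
  cell_ids <- cell_ids %||% rownames(coords) %||%
    paste0("cell_", seq_len(nrow(coords)))
  structure(list(coords = coords, cell_ids = as.character(cell_ids)),
            class = "cg_coords")
}

#' Read chromatin accessibility inputs
#'
#' Assembles the four ingredients of accessibility-based prior networks:
#' a binary cells-by-regions matrix, region genomic intervals (BED,
#' 0-based half-open), a gene TSS table, and region-to-TF motif hits.
#'
#' The TSS table is tab-separated with columns `gene`, `chrom`, `tss`,
#' `strand`; positions are 1-based as in GFF-derived tables and converted
#' to 0-based internally. The motif table is tab-separated with columns
#' `region_index` (1-based row of the BED file) and `tf_name`. Motif hits
#' naming TFs absent from `gene_names` are dropped with a warning.
#'
#' @param region_matrix_path CSV/TSV of the binary cells x regions matrix
#'   (header optional, optional leading cell-id column).
#' @param bed_path BED file of region intervals.
#' @param tss_path TSS table as described above.
#' @param motif_path motif hit table as described above.
#' @param gene_names genes of the expression matrix, used to screen TF names.
#' @return an object of class `cg_accessibility` with fields
#'   `region_matrix`, `region_coords`, `tss_table`, `motif_hits`.
#' @export
read_accessibility <- function(region_matrix_path, bed_path, tss_path,
                               motif_path, gene_names) {
  rm_df <- read.table(region_matrix_path, header = FALSE,
                      sep = guess_sep(region_matrix_path),
                      stringsAsFactors = FALSE)
  # header row of region labels?
  if (!is.numeric(rm_df[[ncol(rm_df)]])) {
    rm_df <- read.table(region_matrix_path, header = TRUE,
                        sep = guess_sep(region_matrix_path),
                        stringsAsFactors = FALSE, check.names = FALSE)
  }
  cell_ids <- NULL
  if (ncol(rm_df) >= 2 && !is.numeric(rm_df[[1]])) {
    cell_ids <- as.character(rm_df[[1]])
    rm_df <- rm_df[, -1, drop = FALSE]
  }
  region_matrix <- as.matrix(rm_df)
  storage.mode(region_matrix) <- "double"
  if (!is.null(cell_ids)) rownames(region_matrix) <- cell_ids

  bed <- read.table(bed_path, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (ncol(bed) < 3) stopf("BED file needs at least 3 columns")
  region_coords <- data.frame(chrom = as.character(bed[[1]]),
                              start = as.integer(bed[[2]]),
                              end = as.integer(bed[[3]]),
                              stringsAsFactors = FALSE)

  tss <- read.table(tss_path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "tss", "strand")
  if (!all(need %in% names(tss)))
    stopf("TSS table must have columns: %s", paste(need, collapse = ", "))
  tss$tss <- as.integer(tss$tss) - 1L   # 1-based input -> 0-based internal

  motif <- read.table(motif_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  if (!all(c("region_index", "tf_name") %in% names(motif)))
    stopf("motif table must have columns region_index, tf_name")

  accessibility_inputs(region_matrix, region_coords, tss, motif, gene_names)
}

#' Construct accessibility inputs from in-memory pieces
#'
#' @param region_matrix binary cells x regions matrix.
#' @param region_coords data frame with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param tss_table data frame with `gene`, `chrom`, `tss` (0-based),
#'   `strand` (`"+"` or `"-"`).
#' @param motif_hits data frame with `region_index` (1-based), `tf_name`.
#' @param gene_names expression gene names used to screen motif TF names.
#' @return an object of class `cg_accessibility`.
#' @export
accessibility_inputs <- function(region_matrix, region_coords, tss_table,
                                 motif_hits, gene_names) {
  region_matrix <- as.matrix(region_matrix)
  if (!all(region_matrix %in% c(0, 1)))
    stopf("region matrix must be binary (0/1)")
  if (ncol(region_matrix) != nrow(region_coords))
    stopf("region matrix has %d regions but BED lists %d",
          ncol(region_matrix), nrow(region_coords))
  if (any(region_coords$start >= region_coords$end))
    stopf("BED rows with start >= end: %s",
          paste(which(region_coords$start >= region_coords$end), collapse = ", "))
  if (anyDuplicated(tss_table$gene))
    stopf("TSS table has duplicated genes")
  if (!all(tss_table$strand %in% c("+", "-")))
    stopf("TSS strand must be '+' or '-'")
  motif_hits$region_index <- as.integer(motif_hits$region_index)
  if (any(motif_hits$region_index < 1 |
          motif_hits$region_index > nrow(region_coords)))
    stopf("motif hit region_index out of range")
  bad <- !(motif_hits$tf_name %in% gene_names)
  if (any(bad)) {
    warnf("dropping %d of %d motif hits naming TFs absent from gene_names (%s)",
          sum(bad), nrow(motif_hits),
          paste(unique(motif_hits$tf_name[bad]), collapse = ", "))
    motif_hits <- motif_hits[!bad, , drop = FALSE]
  }
  structure(list(region_matrix = region_matrix,
                 region_coords = region_coords,
                 tss_table = tss_table,
                 motif_hits = motif_hits),
            class = "cg_accessibility")
}

guess_sep <- function(path) {
  line <- readLines(path, n = 1L)
  if (grepl("\t", line)) "\t" else ","
}

#' Construct a per-cell network tensor
#'
#' Holds one g-by-g matrix per cell: either precision matrices or partial
#' correlation matrices, distinguished by `kind`. Validates symmetry of
#' every slice, positive definiteness for precision tensors, and the
#' `[-1, 1]` range for partial correlations.
#'
#' @param networks numeric array `n_cells x g x g`.
#' @param gene_names,cell_ids identifiers aligned with the array.
#' @param kind `"precision"` or `"partial_correlation"`.
#' @param validate check invariants (disable only for trusted internal use).
#' @return an object of class `cg_grn_tensor`.
#' @export
grn_tensor <- function(networks, gene_names, cell_ids,
                       kind = c("precision", "partial_correlation"),
                       validate = TRUE) {
  kind <- match.arg(kind)
  stopifnot(is.array(networks), length(dim(networks)) == 3L)
  d <- dim(networks)
  if (d[2] != d[3]) stopf("network slices must be square")
  if (length(gene_names) != d[2])
    stopf("expected %d gene names, got %d", d[2], length(gene_names))
  if (length(cell_ids) != d[1])
    stopf("expected %d cell ids, got %d", d[1], length(cell_ids))
  if (validate) {
    for (i in seq_len(d[1])) {
      s <- networks[i, , ]
      if (!is_symmetric_tol(s, 1e-8))
        stopf("network slice %d is not symmetric", i)
      if (kind == "precision") {
        ev <- min(eigen(symmetrize(s), symmetric = TRUE,
                        only.values = TRUE)$values)
        if (ev <= 0)
          stopf("precision slice %d is not positive definite (min eigenvalue %g)",
                i, ev)
      } else {
        off <- s[upper_pairs(d[2])]
        if (any(abs(off) > 1 + 1e-8))
          stopf("partial correlation slice %d has entries outside [-1, 1]", i)
      }
    }
  }
  structure(list(networks = networks,
                 gene_names = as.character(gene_names),
                 cell_ids = as.character(cell_ids),
                 kind = kind),
            class = "cg_grn_tensor")
}

#' Write a network tensor to disk
#'
#' Writes two artifacts: `<out_prefix>.rds`, a compressed archive of the
#' full tensor (exact round trip), and `<out_prefix>_edges.tsv`, a
#' long-format edge table with columns `cell_id`, `gene_a`, `gene_b`,
#' `weight` listing each unordered off-diagonal pair once per cell
#' (`gene_a` lexicographically before `gene_b`).
#'
#' @param tensor a [grn_tensor()] object.
#' @param out_prefix output path prefix.
#' @return invisibly, the two file paths written.
#' @export
write_grn_tensor <- function(tensor, out_prefix) {
  stopifnot(inherits(tensor, "cg_grn_tensor"))
  dir <- dirname(out_prefix)
  if (!dir.exists(dir)) stopf("output directory does not exist: %s", dir)
  rds_path <- paste0(out_prefix, ".rds")
  tsv_path <- paste0(out_prefix, "_edges.tsv")
  saveRDS(tensor, rds_path)

  g <- length(tensor$gene_names)
  n <- length(tensor$cell_ids)
  pairs <- upper_pairs(g)
  a <- tensor$gene_names[pairs[, 1]]
  b <- tensor$gene_names[pairs[, 2]]
  swap <- a > b
  ga <- ifelse(swap, b, a)
  gb <- ifelse(swap, a, b)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    w <- tensor$networks[i, , ][pairs]
    rows[[i]] <- data.frame(cell_id = tensor$cell_ids[i], gene_a = ga,
                            gene_b = gb, weight = w,
                            stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, rows)
  write.table(edges, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(archive = rds_path, edges = tsv_path))
}

#' Read a network tensor written by [write_grn_tensor()]
#'
#' @param out_prefix the prefix passed to [write_grn_tensor()].
#' @return a [grn_tensor()] object, value-identical to the one written.
#' @export
read_grn_tensor <- function(out_prefix) {
  rds_path <- paste0(out_prefix, ".rds")
  if (!file.exists(rds_path)) stopf("archive not found: %s", rds_path)
  tensor <- readRDS(rds_path)
  stopifnot(inherits(tensor, "cg_grn_tensor"))
  tensor
}
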