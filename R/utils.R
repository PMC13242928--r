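# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_symmetric_tol <- function(M, tol = 1e-8) {
  is.matrix(M) && nrow(M) == ncol(M) && max(abs(M - t(M))) <= tol
}

symmetrize <- function(M) (M + t(M)) / 2

# Uniform kernel: every cell informs every other cell equally.
# Corresponds to zero geodesic distance everywhere (bandwidth irrelevant).
uniform_kernel <- function(n) {
  structure(list(
    K = matrix(1, n, n),
    geodesic_D = matrix(0, n, n),
    bandwidth = 1,
    knn_k = n - 1L
  ), class = "cg_kernel")
}

# Upper-triangle index pairs (i < j) as a 2-column integer matrix.
upper_pairs <- function(g) {
  which(upper.tri(matrix(0L, g, g)), arr.ind = TRUE)
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x))
    stopf("`%s` must be a single integer >= %d", name, min)
  as.integer(x)
}

check_positive <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x <= 0)
    stopf("`%s` must be a single positive number", name)
  as.numeric(x)
}
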