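# Internal helpers shared across modules.

# Coerce a counts input to dgCMatrix (cells x features). Accepts dense
# matrices, sparse Matrix classes, or a data.frame of numerics.
as_counts <- function(x, arg = "counts") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.matrix(x)) x <- methods::as(x, "CsparseMatrix")
  if (!methods::is(x, "CsparseMatrix")) {
    abort(sprintf("`%s` must be a matrix or sparse Matrix (cells x features).", arg))
  }
  x
}

# Dense numeric matrix, for the linear-algebra-heavy paths.
as_dense <- function(x) {
  if (methods::is(x, "Matrix")) as.matrix(x) else as.matrix(x)
}

require_columns <- function(df, cols, arg = "data") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("`%s` is missing required column(s): %s",
                  arg, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# Run `expr` under a locally-seeded RNG without disturbing the caller's stream.
with_seed_local <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

#' Scale each cell's counts to a fixed total
#'
#' @param counts Cells x features count matrix.
#' @param scale_to Target per-cell total (default 10,000).
#' @return Sparse cells x features matrix of normalized counts.
#' @export
normalize_per_cell <- function(counts, scale_to = 1e4) {
  counts <- as_counts(counts)
  totals <- Matrix::rowSums(counts)
  totals[totals == 0] <- 1
  Matrix::Diagonal(x = scale_to / totals) %*% counts
}

#' Depth-scale and log-transform a count matrix
#'
#' Per-cell scaling to `scale_to` followed by `log(x + 1)` in the given base
#' (2 for atlas-style preprocessing, `exp(1)` for knockout-style).
#'
#' @inheritParams normalize_per_cell
#' @param base Logarithm base.
#' @return Sparse cells x features matrix.
#' @export
log_normalize <- function(counts, scale_to = 1e4, base = 2) {
  x <- normalize_per_cell(counts, scale_to)
  x@x <- log1p(x@x) / log(base)
  x
}

# Nearest-neighbour indices of each row of `query` among rows of `ref`,
# by Euclidean distance, computed blockwise with dense algebra.
knn_indices <- function(query, ref, k, block = 512L) {
  query <- as_dense(query); ref <- as_dense(ref)
  if (k > nrow(ref)) abort("`k` exceeds the number of reference points.")
  ref_sq <- rowSums(ref^2)
  out <- matrix(0L, nrow(query), k)
  for (start in seq(1L, nrow(query), by = block)) {
    idx <- start:min(start + block - 1L, nrow(query))
    d2 <- outer(rowSums(query[idx, , drop = FALSE]^2), ref_sq, "+") -
      2 * query[idx, , drop = FALSE] %*% Matrix::t(ref)
    out[idx, ] <- Matrix::t(apply(d2, 1, function(z) order(z)[seq_len(k)]))
  }
  out
}
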