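#' Bin cells into equal-count pseudotime bins
#'
#' Cells are ordered by pseudotime (ties broken by stable input order) and
#' split into `n_bins` contiguous rank bins whose sizes differ by at most 1.
#' Bin index is monotone non-decreasing in pseudotime.
#'
#' @param pseudotime Per-cell pseudotime values (any total ordering).
#' @param n_bins Number of bins (default 20).
#' @return Integer bin assignment (1..`n_bins`), in input cell order.
#' @export
bin_pseudotime <- function(pseudotime, n_bins = 20) {
  n <- length(pseudotime)
  if (n_bins > n) abort("More bins than cells.")
  r <- rank(pseudotime, ties.method = "first")
  as.integer(floor((r - 1) * n_bins / n) + 1)
}

#' Screen for pseudotime-dynamic genes
#'
#' Cells are grouped into `n_periods` equal-count pseudotime periods. Per
#' gene, `max_fold_change = log2(max period mean + 1) - log2(min period mean
#' + 1)` on depth-normalized expression, and a q-value from a rank-based
#' one-way across-period location test (Kruskal-Wallis), BH-adjusted. Genes
#' pass when `max_fold_change > min_log2_fc` and `q < max_q`; constant genes
#' get q = 1 and never pass.
#'
#' @param counts Cells x genes count matrix.
#' @param pseudotime Per-cell pseudotime.
#' @param n_periods Number of screen periods (default 20).
#' @param min_log2_fc,max_q Selection thresholds (defaults 0.75, 0.01).
#' @param scale_to Per-cell depth-scaling total.
#' @return Tibble: `gene`, `max_fold_change`, `p_value`, `q_value`,
#'   `selected`.
#' @export
dynamic_genes <- function(counts, pseudotime, n_periods = 20,
                          min_log2_fc = 0.75, max_q = 0.01, scale_to = 1e4) {
  X <- as_dense(normalize_per_cell(as_counts(counts), scale_to))
  period <- bin_pseudotime(pseudotime, n_periods)
  period_mean <- apply(X, 2, function(v) tapply(v, period, mean))
  mfc <- log2(apply(period_mean, 2, max) + 1) - log2(apply(period_mean, 2, min) + 1)
  pf <- factor(period)
  p <- apply(X, 2, function(v) {
    if (all(v == v[1])) return(1)
    stats::kruskal.test(v, pf)$p.value
  })
  q <- p.adjust(p, "BH")
  genes <- colnames(X) %||% sprintf("gene%d", seq_along(p))
  tibble(gene = genes, max_fold_change = unname(mfc),
         p_value = unname(p), q_value = unname(q),
         selected = unname(mfc > min_log2_fc & q < max_q))
}

#' Sum raw counts into pseudobulk profiles by group
#'
#' @param counts Cells x genes count matrix.
#' @param groups Per-cell group labels (e.g. pseudotime bin or genotype).
#' @return Dense genes x groups matrix of summed raw counts.
#' @export
pseudobulk_profiles <- function(counts, groups) {
  X <- as_counts(counts)
  labs <- sort(unique(as.character(groups)))
  out <- sapply(labs, function(l) {
    Matrix::colSums(X[as.character(groups) == l, , drop = FALSE])
  })
  if (is.null(dim(out))) out <- matrix(out, ncol = 1, dimnames = list(colnames(X), labs))
  out
}

#' Stage genotype pseudobulks against atlas pseudotime bins
#'
#' Each profile (genotype or bin pseudobulk) is restricted to the dynamic
#' gene set and rank-transformed; Pearson correlation of rank vectors (i.e.
#' a Spearman-type association) is computed between every genotype and every
#' bin, and the two bins with the largest correlation are reported per
#' genotype.
#'
#' @param genotype_bulks Genes x genotypes matrix of summed raw counts.
#' @param bin_bulks Genes x bins matrix of summed raw counts.
#' @param dynamic_set Character vector of dynamic genes (must be rownames of
#'   both matrices).
#' @return Tibble of class `stage_assignment`: `genotype`, `bin`,
#'   `correlation`, `top2` (logical: among that genotype's two best bins).
#' @export
stage_correlate <- function(genotype_bulks, bin_bulks, dynamic_set) {
  G <- as_dense(genotype_bulks); B <- as_dense(bin_bulks)
  if (ncol(B) < 2) abort("Need at least 2 pseudotime bins.")
  genes <- intersect(dynamic_set, intersect(rownames(G), rownames(B)))
  if (length(genes) < 3) abort("Fewer than 3 dynamic genes shared by the profiles.")
  Gr <- apply(G[genes, , drop = FALSE], 2, rank)
  Br <- apply(B[genes, , drop = FALSE], 2, rank)
  cc <- cor(Gr, Br)  # genotypes x bins
  out <- as_tibble(as.data.frame.table(cc, responseName = "correlation",
                                       stringsAsFactors = FALSE)) |>
    dplyr::rename(genotype = "Var1", bin = "Var2") |>
    group_by(.data$genotype) |>
    mutate(top2 = rank(-.data$correlation, ties.method = "first") <= 2) |>
    ungroup()
  class(out) <- c("stage_assignment", class(out))
  out
}
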