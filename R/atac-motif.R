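#' Bias-corrected motif deviation z-scores
#'
#' chromVAR-style per-cell motif accessibility scores. For each motif the raw
#' deviation in a cell is `(observed - expected) / expected`, where observed
#' is the cell's total accessibility in motif-carrying peaks and expected
#' assumes cell-independent peak usage (cell total times the motif peaks'
#' share of all insertions). Technical bias is removed with `n_background`
#' background peak sets matched on GC content and mean accessibility
#' (10 x 10 decile bins, sampled with replacement within a bin): the z-score
#' of the raw deviation against the background deviations is returned.
#'
#' @param peak_counts Cells x peaks count matrix.
#' @param motif_hits Binary peaks x motifs matrix (dense or sparse).
#' @param gc Per-peak GC fraction (length = number of peaks).
#' @param n_background Number of background sets (default 50).
#' @param bins Number of GC (and accessibility) decile bins.
#' @param seed Seed for background sampling.
#' @return Object of class `deviation_scores`: `z` and `raw` (motifs x cells
#'   matrices; motifs with zero hits are `NA`), plus the background `bin`
#'   assignment per peak.
#' @export
motif_deviations <- function(peak_counts, motif_hits, gc,
                             n_background = 50, bins = 10, seed = 1L) {
  X <- as_counts(peak_counts)
  H <- methods::as(methods::as(motif_hits, "CsparseMatrix"), "dMatrix")
  stopifnot(ncol(X) == nrow(H), length(gc) == ncol(X))
  peak_tot <- Matrix::colSums(X)
  cell_tot <- Matrix::rowSums(X)
  grand <- sum(peak_tot)
  if (grand == 0) abort("Empty count matrix.")

  dev_of <- function(hits) {
    obs <- Matrix::t(X %*% hits)                  # motifs x cells
    expc <- (Matrix::t(hits) %*% peak_tot) / grand # motif share of insertions
    expected <- as.matrix(expc %*% matrix(cell_tot, 1))
    d <- (as.matrix(obs) - expected) / expected
    d[expected == 0] <- NA_real_
    d
  }
  raw <- dev_of(H)

  ## background bins: GC deciles x accessibility deciles
  decile <- function(v) {
    as.integer(cut(rank(v, ties.method = "first"), breaks = bins,
                   labels = FALSE, include.lowest = TRUE))
  }
  bin <- paste(decile(gc), decile(peak_tot))
  bin_members <- split(seq_len(ncol(X)), bin)

  n_peaks <- ncol(X)
  bg_dev <- with_seed_local(seed, {
    lapply(seq_len(n_background), function(b) {
      bg <- integer(n_peaks)
      for (members in bin_members) {
        bg[members] <- members[sample.int(length(members), length(members),
                                          replace = TRUE)]
      }
      S <- Matrix::sparseMatrix(i = seq_len(n_peaks), j = bg, x = 1,
                                dims = c(n_peaks, n_peaks))
      dev_of(Matrix::crossprod(S, H))
    })
  })
  arr <- simplify2array(bg_dev)                  # motifs x cells x n_background
  bg_mean <- apply(arr, c(1, 2), mean)
  bg_sd <- apply(arr, c(1, 2), sd)
  z <- (raw - bg_mean) / bg_sd
  z[!is.finite(z)] <- NA_real_

  no_hits <- Matrix::colSums(H) == 0
  if (any(no_hits)) {
    warn(sprintf("%d motif(s) have zero hits; their scores are NA.", sum(no_hits)))
    z[no_hits, ] <- NA_real_
    raw[no_hits, ] <- NA_real_
  }
  rownames(z) <- rownames(raw) <- colnames(H)
  colnames(z) <- colnames(raw) <- rownames(X)
  structure(list(z = z, raw = raw, bin = bin, n_background = n_background),
            class = "deviation_scores")
}

#' @export
print.deviation_scores <- function(x, ...) {
  cat(sprintf("Motif deviation scores: %d motifs x %d cells (%d background sets)\n",
              nrow(x$z), ncol(x$z), x$n_background))
  invisible(x)
}

#' Pair motifs with same-family genes by deviation/expression agreement
#'
#' Per-cluster motif score = the motif's mean deviation z-score in that
#' cluster minus the minimum cluster mean (so the flattest cluster scores 0).
#' Each motif is paired with its best-correlated same-family gene (deviation
#' z vs expression across cells), assigned to the cluster where its motif
#' score peaks; when several motifs claim one gene, the motif with the higher
#' peak score wins. A pair is retained when the correlation exceeds
#' `corr_cutoff` and its motif score sits in the top decile of that cluster's
#' scores (boundary ties included).
#'
#' @param deviations A [motif_deviations()] result (or a motifs x cells
#'   z-score matrix).
#' @param expression Cells x genes expression matrix (same cells).
#' @param clusters Per-cell cluster labels.
#' @param family_map Tibble with `motif`, `gene` columns listing same-family
#'   candidate pairs.
#' @param corr_cutoff Minimum motif-gene correlation (default 0.35).
#' @param percentile_cutoff Cluster-score percentile a retained pair must
#'   reach (default 0.9, i.e. top-10 percentile).
#' @return Tibble: `motif`, `gene`, `cluster`, `correlation`, `motif_score`,
#'   `retained`.
#' @export
motif_gene_pairing <- function(deviations, expression, clusters, family_map,
                               corr_cutoff = 0.35, percentile_cutoff = 0.9) {
  z <- if (inherits(deviations, "deviation_scores")) deviations$z else as_dense(deviations)
  E <- as_dense(expression)
  require_columns(family_map, c("motif", "gene"), "family_map")
  fam <- dplyr::filter(family_map, .data$motif %in% rownames(z),
                       .data$gene %in% colnames(E))
  if (!nrow(fam)) {
    warn("No motif-gene family pair overlaps the data; empty result.")
    return(tibble(motif = character(), gene = character(), cluster = character(),
                  correlation = numeric(), motif_score = numeric(),
                  retained = logical()))
  }
  labs <- sort(unique(as.character(clusters)))

  ## cluster-mean deviation per motif, and the per-cluster motif score
  cl_mean <- sapply(labs, function(l) {
    rowMeans(z[, as.character(clusters) == l, drop = FALSE], na.rm = TRUE)
  })
  if (is.null(dim(cl_mean))) cl_mean <- matrix(cl_mean, nrow = nrow(z),
                                               dimnames = list(rownames(z), labs))
  score <- cl_mean - apply(cl_mean, 1, min)

  fam$correlation <- vapply(seq_len(nrow(fam)), function(i) {
    suppressWarnings(cor(z[fam$motif[i], ], E[, fam$gene[i]],
                         use = "complete.obs"))
  }, numeric(1))

  ## per motif: best-correlated gene; assignment cluster = argmax motif score
  best_gene <- fam |>
    group_by(.data$motif) |>
    dplyr::slice_max(.data$correlation, n = 1, with_ties = FALSE) |>
    ungroup()
  best_gene$cluster <- labs[apply(score[best_gene$motif, , drop = FALSE], 1, which.max)]
  best_gene$motif_score <- score[cbind(best_gene$motif, best_gene$cluster)]

  ## per gene: keep the motif with the top peak score
  pairs <- best_gene |>
    group_by(.data$gene) |>
    dplyr::slice_max(.data$motif_score, n = 1, with_ties = FALSE) |>
    ungroup()

  ## top-decile membership within the assignment cluster, ties inclusive
  thresh <- apply(score, 2, quantile, probs = percentile_cutoff, na.rm = TRUE)
  pairs$retained <- pairs$correlation > corr_cutoff &
    pairs$motif_score >= thresh[pairs$cluster]
  select(pairs, "motif", "gene", "cluster", "correlation", "motif_score", "retained")
}
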