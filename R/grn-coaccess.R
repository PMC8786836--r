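#' Sample low-overlapping aggregates of cells
#'
#' Cicero-style aggregation: up to `n_iterations` random seed cells are
#' drawn; each candidate aggregate is the seed plus its `k - 1` nearest
#' neighbours in the reduced space, and it is accepted only if its overlap
#' fraction `|A . B| / k` with every previously accepted aggregate is at most
#' `overlap_cutoff`.
#'
#' @param coords Cells x dimensions matrix of reduced coordinates.
#' @param k Cells per aggregate (default 100).
#' @param n_iterations Number of seed draws (default 500).
#' @param overlap_cutoff Maximum pairwise overlap fraction (default 0.8).
#' @param seed Integer seed.
#' @return List of integer cell-index vectors (class `cell_aggregates`).
#' @export
sample_aggregates <- function(coords, k = 100, n_iterations = 500,
                              overlap_cutoff = 0.8, seed = 1L) {
  coords <- as_dense(coords)
  n <- nrow(coords)
  if (n < k) abort("Fewer cells than the aggregate size `k`.")
  nn <- knn_indices(coords, coords, k)  # includes self as first neighbour
  accepted <- list()
  member_mat <- matrix(FALSE, n_iterations, n)  # accepted x cells, preallocated
  n_acc <- 0L
  with_seed_local(seed, {
    seeds <- sample.int(n, n_iterations, replace = n_iterations > n)
    for (s in seeds) {
      cand <- nn[s, ]
      if (n_acc > 0L) {
        ov <- rowSums(member_mat[seq_len(n_acc), cand, drop = FALSE])
        if (max(ov) / k > overlap_cutoff) next
      }
      n_acc <- n_acc + 1L
      accepted[[n_acc]] <- cand
      member_mat[n_acc, cand] <- TRUE
    }
  })
  structure(accepted, class = "cell_aggregates", n_cells = n, k = k)
}

#' Peak-peak co-accessibility across cell aggregates
#'
#' Aggregate accessibility is the per-aggregate summed insertion count,
#' depth-scaled and log2-transformed. Pearson correlations are computed for
#' peak pairs on the same chromosome whose midpoints lie within
#' `max_distance`; p-values come from the correlation t-statistic
#' (df = number of aggregates - 2) and are BH-adjusted. A pair is retained
#' when FDR < `fdr_max`, both peaks exceed the `variability_min` variance
#' quantile across aggregates, and the correlation is at least `corr_min`.
#'
#' @param peak_counts Cells x peaks count matrix.
#' @param aggregates A [sample_aggregates()] result (or list of index vectors).
#' @param peaks Peak table (`peak`, `chrom`, `start`, `end`), rows matching
#'   the columns of `peak_counts`.
#' @param max_distance Midpoint distance cap in bp (default 250,000).
#' @param fdr_max Retain pairs with BH-adjusted p strictly below this.
#' @param variability_min Variance quantile below which a peak is considered
#'   too flat (default 0.35).
#' @param corr_min Minimum correlation (default 0.5).
#' @param scale_to Aggregate depth-scaling total.
#' @param return_all Return all tested pairs with a `retained` flag instead
#'   of only the retained ones.
#' @return Tibble: `peak1`, `peak2` (canonical order: `peak1` earlier in the
#'   peak table), `correlation`, `p_value`, `fdr` (+ `retained` when
#'   `return_all`).
#' @export
compute_coaccessibility <- function(peak_counts, aggregates, peaks,
                                    max_distance = 250000, fdr_max = 1e-10,
                                    variability_min = 0.35, corr_min = 0.5,
                                    scale_to = 1e4, return_all = FALSE) {
  X <- as_counts(peak_counts)
  if (length(aggregates) < 3) abort("Need at least 3 aggregates.")
  require_columns(peaks, c("peak", "chrom", "start", "end"), "peaks")
  stopifnot(nrow(peaks) == ncol(X))

  agg <- t(vapply(aggregates, function(idx) {
    Matrix::colSums(X[idx, , drop = FALSE])
  }, numeric(ncol(X))))
  tot <- rowSums(agg); tot[tot == 0] <- 1
  agg <- log2(agg * (scale_to / tot) + 1)
  n_agg <- nrow(agg)

  ## candidate pairs: same chromosome, midpoints within max_distance
  mid <- (peaks$start + peaks$end) / 2
  pairs <- lapply(split(seq_len(nrow(peaks)), peaks$chrom), function(idx) {
    idx <- idx[order(mid[idx])]
    out <- list()
    j0 <- 1L
    for (a in seq_along(idx)) {
      b <- a + 1L
      while (b <= length(idx) && mid[idx[b]] - mid[idx[a]] <= max_distance) {
        out[[length(out) + 1L]] <- c(idx[a], idx[b])
        b <- b + 1L
      }
    }
    if (length(out)) do.call(rbind, out)
  })
  pairs <- do.call(rbind, pairs[!vapply(pairs, is.null, logical(1))])
  if (is.null(pairs) || !nrow(pairs)) {
    return(tibble(peak1 = character(), peak2 = character(),
                  correlation = numeric(), p_value = numeric(), fdr = numeric()))
  }
  i <- pmin(pairs[, 1], pairs[, 2]); j <- pmax(pairs[, 1], pairs[, 2])

  sds <- apply(agg, 2, sd)
  centered <- sweep(agg, 2, colMeans(agg))
  denom <- sds * sqrt(n_agg - 1)
  r <- unname(colSums(centered[, i, drop = FALSE] * centered[, j, drop = FALSE]) /
                (denom[i] * denom[j]))
  r[!is.finite(r)] <- NA_real_
  tstat <- r * sqrt((n_agg - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n_agg - 2)
  fdr <- p.adjust(p, "BH")

  ## variability as the peak's variance quantile across the peak set:
  ## the lowest `variability_min` fraction is considered too flat
  var_rank <- rank(sds^2, ties.method = "max") / length(sds)
  retained <- !is.na(r) & fdr < fdr_max & r >= corr_min &
    var_rank[i] > variability_min & var_rank[j] > variability_min

  out <- tibble(peak1 = peaks$peak[i], peak2 = peaks$peak[j],
                correlation = r, p_value = p, fdr = fdr)
  if (return_all) {
    out$retained <- retained
    out
  } else {
    out[retained, , drop = FALSE]
  }
}
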