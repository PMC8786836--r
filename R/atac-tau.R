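#' Cluster-averaged, depth-scaled, log2-transformed signal profiles
#'
#' Per-cluster mean of depth-normalized counts, then `log2(x + 1)`: the
#' matrix the cluster-specificity index is computed on.
#'
#' @param counts Cells x features count matrix.
#' @param clusters Per-cell cluster labels.
#' @param scale_to Per-cell total after depth scaling.
#' @return Dense features x clusters matrix.
#' @export
cluster_mean_profile <- function(counts, clusters, scale_to = 1e4) {
  norm <- normalize_per_cell(as_counts(counts), scale_to)
  labs <- sort(unique(as.character(clusters)))
  out <- sapply(labs, function(l) {
    Matrix::colMeans(norm[as.character(clusters) == l, , drop = FALSE])
  })
  log2(out + 1)
}

#' Cluster specificity index (tau)
#'
#' For each feature, signals are max-normalized across clusters
#' (`x_i = m_i / max_i m_i`) and `tau = sum(1 - x_i) / (N - 1)`:
#' 0 for a feature equally active in every cluster, 1 for a feature active
#' in exactly one.
#'
#' @param profile Features x clusters matrix of (log-scale) mean signal,
#'   e.g. from [cluster_mean_profile()]. Values must be non-negative.
#' @return Tibble: `feature`, `tau` (`NA` for all-zero features).
#' @export
tau_index <- function(profile) {
  m <- as_dense(profile)
  if (ncol(m) < 2) abort("tau needs at least 2 clusters.")
  if (any(m < 0)) abort("tau expects non-negative signal values.")
  mx <- apply(m, 1, max)
  x <- m / ifelse(mx > 0, mx, 1)
  tau <- rowSums(1 - x) / (ncol(m) - 1)
  tau[mx == 0] <- NA_real_
  tibble(feature = rownames(m) %||% sprintf("feature%d", seq_len(nrow(m))),
         tau = unname(tau))
}

#' Filter peaks by mean per-base conservation score
#'
#' Averages a per-base conservation track over each peak span (bases not
#' covered by the track count as 0) and retains peaks whose mean is strictly
#' above the threshold.
#'
#' @param peaks Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param scores Conservation track as a bedGraph-style tibble (`chrom`,
#'   `start`, `end`, `score`), 0-based half-open.
#' @param threshold Retain peaks with mean score strictly greater than this.
#' @param return_all If `TRUE`, return all peaks with `mean_score` and
#'   `retained` columns; otherwise only the retained peaks.
#' @return Tibble of peaks with a `mean_score` column.
#' @export
conservation_filter <- function(peaks, scores, threshold = 0.5,
                                return_all = FALSE) {
  peaks <- as_tibble(peaks)
  require_columns(peaks, c("chrom", "start", "end"), "peaks")
  require_columns(scores, c("chrom", "start", "end", "score"), "scores")
  pk <- to_granges(peaks)
  sc <- to_granges(scores)
  hits <- GenomicRanges::findOverlaps(pk, sc)
  total <- numeric(nrow(peaks))
  if (length(hits)) {
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    ov <- pmin(peaks$end[q], scores$end[s]) - pmax(peaks$start[q], scores$start[s])
    total <- as.numeric(tapply(ov * scores$score[s], factor(q, seq_len(nrow(peaks))),
                               sum, default = 0))
  }
  peaks$mean_score <- total / (peaks$end - peaks$start)
  retained <- peaks$mean_score > threshold
  if (return_all) {
    peaks$retained <- retained
    peaks
  } else {
    peaks[retained, , drop = FALSE]
  }
}
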