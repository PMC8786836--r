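#' Classify query cells by k-nearest-neighbour plurality vote in an atlas
#'
#' Each query cell's `k` nearest atlas cells (Euclidean distance in the
#' shared principal subspace) vote for their cluster labels; the vote
#' fractions are the label probabilities and the plurality label is
#' assigned (ties broken toward the lowest cluster label, so results are
#' deterministic). When a 2-D atlas embedding is supplied, each query cell is
#' placed at the mean embedding position of its neighbours.
#'
#' @param query_coords Query cells x dims coordinates (from
#'   [project_cells()]).
#' @param atlas_coords Atlas cells x dims coordinates in the same subspace.
#' @param atlas_labels Per-atlas-cell cluster labels.
#' @param atlas_embedding Optional atlas cells x 2 embedding (e.g. UMAP).
#' @param k Number of neighbours (default 50).
#' @return Object of class `projection_result`: `cells` (tibble `cell`,
#'   `label`, and `x`/`y` when an embedding was given) and `prob`
#'   (query cells x clusters vote-fraction matrix, rows summing to 1).
#' @export
classify_knn <- function(query_coords, atlas_coords, atlas_labels,
                         atlas_embedding = NULL, k = 50) {
  Q <- as_dense(query_coords); A <- as_dense(atlas_coords)
  if (k > nrow(A)) abort("`k` exceeds the atlas size.")
  stopifnot(length(atlas_labels) == nrow(A))
  labs <- sort(unique(as.character(atlas_labels)))
  nn <- knn_indices(Q, A, k)
  lab_mat <- matrix(as.character(atlas_labels)[nn], nrow(Q), k)
  prob <- t(apply(lab_mat, 1, function(v) {
    tabulate(factor(v, levels = labs), nbins = length(labs))
  })) / k
  colnames(prob) <- labs
  label <- labs[apply(prob, 1, which.max)]  # which.max -> lowest label on ties
  cells <- tibble(cell = rownames(Q) %||% sprintf("query%05d", seq_len(nrow(Q))),
                  label = label)
  if (!is.null(atlas_embedding)) {
    Emb <- as_dense(atlas_embedding)
    cells$x <- rowMeans(matrix(Emb[nn, 1], nrow(Q), k))
    cells$y <- rowMeans(matrix(Emb[nn, 2], nrow(Q), k))
  }
  rownames(prob) <- cells$cell
  structure(list(cells = cells, prob = prob, k = k),
            class = "projection_result")
}

#' @export
print.projection_result <- function(x, ...) {
  cat(sprintf("Projection of %d query cells onto %d atlas clusters (k = %d)\n",
              nrow(x$cells), ncol(x$prob), x$k))
  invisible(x)
}

#' @describeIn classify_knn Long per-cell per-cluster probabilities.
#' @param x A `projection_result`.
#' @param ... Unused.
#' @export
tidy.projection_result <- function(x, ...) {
  as_tibble(as.data.frame.table(x$prob, responseName = "probability",
                                stringsAsFactors = FALSE)) |>
    dplyr::rename(cell = "Var1", cluster = "Var2")
}

#' Cluster-abundance confidence intervals from a quasi-Poisson GLM
#'
#' Per cluster, the response in each replicate is the summed label
#' probability of that replicate's cells multiplied by the neighbour count
#' `k` and rounded (so probabilistic assignments become whole numbers); a
#' quasi-Poisson log-link GLM of response on genotype (+ batch when present)
#' with offset `log(replicate total cells)` gives the genotype log fold
#' change with an asymptotic Wald interval scaled by the Pearson dispersion.
#'
#' @param result A [classify_knn()] `projection_result`.
#' @param cells Per-cell metadata tibble with `cell`, `replicate`,
#'   `genotype`, and optionally `batch` columns, matching the query cells.
#' @param k Neighbour count used for the vote (defaults to the result's).
#' @param conf Confidence level (default 0.95).
#' @param min_count Clusters with fewer than this many total (probability-
#'   weighted) cells are flagged.
#' @param log_base Base of the reported fold change (default natural log).
#' @return Tibble of class `abundance_estimate`: `cluster`, `estimate`,
#'   `lower`, `upper`, `dispersion`, `total_count`, `flagged`. Clusters
#'   where one genotype has no cells get `NA` estimates and a flag.
#' @export
abundance_ci <- function(result, cells, k = NULL, conf = 0.95,
                         min_count = 100, log_base = exp(1)) {
  stopifnot(inherits(result, "projection_result"))
  cells <- as_tibble(cells)
  require_columns(cells, c("cell", "replicate", "genotype"), "cells")
  k <- k %||% result$k
  prob <- result$prob[match(cells$cell, rownames(result$prob)), , drop = FALSE]
  if (anyNA(prob[, 1])) abort("`cells` contains cells absent from the projection result.")
  has_batch <- "batch" %in% names(cells)

  rep_info <- cells |>
    group_by(.data$replicate) |>
    summarise(genotype = .data$genotype[1],
              batch = if (has_batch) .data$batch[1] else NA,
              total = n(), .groups = "drop")
  z <- stats::qnorm(1 - (1 - conf) / 2)

  out <- lapply(colnames(prob), function(cl) {
    resp <- tapply(prob[, cl], cells$replicate, sum)
    resp <- round(resp[rep_info$replicate] * k)
    dat <- data.frame(resp = as.numeric(resp),
                      genotype = factor(rep_info$genotype),
                      total = rep_info$total)
    if (has_batch) dat$batch <- factor(rep_info$batch)
    total_count <- sum(prob[, cl])
    ## a genotype entirely empty for this cluster: estimate diverges
    by_geno <- tapply(dat$resp, dat$genotype, sum)
    if (any(by_geno == 0)) {
      return(tibble(cluster = cl, estimate = NA_real_, lower = NA_real_,
                    upper = NA_real_, dispersion = NA_real_,
                    total_count = total_count, flagged = TRUE))
    }
    form <- if (has_batch && nlevels(dat$batch) > 1) {
      resp ~ genotype + batch
    } else resp ~ genotype
    fit <- glm(form, family = quasipoisson(), data = dat,
               offset = log(dat$total))
    sm <- summary(fit)
    co <- sm$coefficients
    g_row <- grep("^genotype", rownames(co))[1]
    est <- co[g_row, "Estimate"]; se <- co[g_row, "Std. Error"]
    tibble(cluster = cl,
           estimate = est / log(log_base),
           lower = (est - z * se) / log(log_base),
           upper = (est + z * se) / log(log_base),
           dispersion = sm$dispersion,
           total_count = total_count,
           flagged = total_count < min_count)
  })
  out <- bind_rows(out)
  class(out) <- c("abundance_estimate", class(out))
  out
}

#' Retain cells by summed cluster probability and a sentinel gene
#'
#' A query cell is kept when the sum of its label probabilities over
#' `score_clusters` is at least `min_score` *and* the sentinel gene is
#' detected (count > 0).
#'
#' @param result A [classify_knn()] `projection_result`.
#' @param counts Query cells x genes count matrix (rownames = cell ids).
#' @param score_clusters Cluster labels whose probabilities are summed.
#' @param min_score Inclusive probability threshold (default 0.8).
#' @param sentinel_gene Gene that must be detected (default `"Il7"`).
#' @return Character vector of retained cell ids.
#' @export
thymus_filter <- function(result, counts, score_clusters, min_score = 0.8,
                          sentinel_gene = "Il7") {
  stopifnot(inherits(result, "projection_result"))
  counts <- as_counts(counts)
  if (!sentinel_gene %in% colnames(counts)) {
    abort(sprintf("Sentinel gene `%s` absent from the count matrix.", sentinel_gene))
  }
  score_clusters <- intersect(as.character(score_clusters), colnames(result$prob))
  score <- Matrix::rowSums(result$prob[, score_clusters, drop = FALSE])
  ids <- rownames(result$prob)
  detected <- as.numeric(counts[match(ids, rownames(counts)), sentinel_gene]) > 0
  ids[score >= min_score & detected %in% TRUE]
}
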