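#' Build the batch-correction covariate design matrix
#'
#' One column for the per-cell total UMI count, three cell-cycle phase
#' indicator columns (G1/S/G2M; all three are kept and identifiability is
#' left to downstream rank handling), and, for each timepoint with `r`
#' replicates, `r - 1` replicate contrast columns: contrast `j` is +1 for
#' cells of replicate `j`, -1 for replicate `j + 1`, 0 elsewhere (the
#' redundant further contrasts lie in the span of these and are omitted).
#' With replicate structure (2, 3, 3, 2) this yields 6 contrast columns and
#' a total of d = 10.
#'
#' @param cells Metadata tibble with `total_umi`, `cell_cycle_phase`,
#'   `timepoint`, `replicate` columns (names configurable).
#' @param umi_col,phase_col,timepoint_col,replicate_col Column names.
#' @param scale_umi Standardize the UMI column (does not change the span).
#' @return A numeric cells x d matrix of class `covariate_design`, with a
#'   `roles` attribute naming each column's role.
#' @export
build_design <- function(cells, umi_col = "total_umi",
                         phase_col = "cell_cycle_phase",
                         timepoint_col = "timepoint",
                         replicate_col = "replicate",
                         scale_umi = TRUE) {
  cells <- as_tibble(cells)
  require_columns(cells, c(umi_col, phase_col, timepoint_col, replicate_col), "cells")
  n <- nrow(cells)
  umi <- as.numeric(cells[[umi_col]])
  if (scale_umi) umi <- as.numeric(scale(umi))

  phases <- c("G1", "S", "G2M")
  phase_mat <- sapply(phases, function(p) as.numeric(cells[[phase_col]] == p))
  if (n == 1) phase_mat <- matrix(phase_mat, nrow = 1, dimnames = list(NULL, phases))

  tp <- as.character(cells[[timepoint_col]])
  rep_id <- cells[[replicate_col]]
  contrasts <- list()
  for (t in unique(tp)) {
    reps <- sort(unique(rep_id[tp == t]))
    if (length(reps) < 2) next
    for (j in seq_len(length(reps) - 1)) {
      col <- numeric(n)
      col[tp == t & rep_id == reps[j]] <- 1
      col[tp == t & rep_id == reps[j + 1]] <- -1
      contrasts[[sprintf("%s_rep%s_vs_rep%s", t, reps[j], reps[j + 1])]] <- col
    }
  }
  design <- cbind(total_umi = umi, phase_mat,
                  if (length(contrasts)) do.call(cbind, contrasts))
  roles <- c("total_umi", rep("cell_cycle", 3),
             rep("replicate_contrast", length(contrasts)))
  structure(design, roles = roles, class = c("covariate_design", class(design)))
}

# Fitted-value projector for a design (plus intercept), via pivoted QR so
# rank-deficient designs are handled by dropping dependent columns. The three
# phase indicators always sum to the intercept, so one unit of deficiency is
# expected and not worth a warning.
design_qr <- function(design, n, warn_deficient = TRUE) {
  X <- cbind(intercept = rep(1, n), if (!is.null(design)) unclass(design))
  qr_x <- qr(X)
  expected <- ncol(X)
  roles <- attr(design, "roles")
  if (!is.null(roles) && sum(roles == "cell_cycle") == 3) expected <- expected - 1L
  if (qr_x$rank < expected && warn_deficient) {
    warn(sprintf("Design is rank-deficient (%d of %d columns independent); dependent columns dropped.",
                 qr_x$rank, ncol(X)))
  }
  qr_x
}

#' Select variable genes by residual dispersion after covariate regression
#'
#' The classic variable-gene rule operates on normalized (depth-scaled, not
#' log-transformed) counts, computing per-gene dispersion `log(variance /
#' mean)` and z-scoring it within 20 equal-count mean bins. Here the variance
#' is replaced by the variance of residuals from a least-squares regression
#' of each gene on the covariate design, so variation explained by depth,
#' cell cycle or replicate batch does not inflate the selection.
#'
#' @param norm_counts Cells x genes matrix of normalized counts (scaled to
#'   e.g. 10,000 per cell, *not* log-transformed).
#' @param design A [build_design()] matrix, or `NULL` for the plain rule
#'   (residual variance is then the mean-centered variance).
#' @param mean_cutoff,dispersion_cutoff Selection thresholds on the gene mean
#'   and the bin-scaled dispersion.
#' @param n_bins Number of equal-count mean bins for dispersion scaling.
#' @return Tibble: `gene`, `mean`, `dispersion`, `dispersion_scaled`,
#'   `selected`. Zero-residual-variance genes get `dispersion = -Inf` and are
#'   never selected.
#' @export
select_genes_residual_dispersion <- function(norm_counts, design = NULL,
                                             mean_cutoff = 0.1,
                                             dispersion_cutoff = 0.8,
                                             n_bins = 20) {
  X <- as_dense(norm_counts)
  n <- nrow(X)
  gene_mean <- colMeans(X)
  qr_x <- design_qr(design, n, warn_deficient = FALSE)
  resid <- qr.resid(qr_x, X)
  res_var <- colSums(resid^2) / (n - 1)
  ## an exactly-fitted gene leaves numerical dust, not true residual variance
  tot_var <- colSums(sweep(X, 2, gene_mean)^2) / (n - 1)
  res_var[res_var <= tot_var * 1e-12] <- 0
  dispersion <- ifelse(res_var > 0 & gene_mean > 0,
                       log(res_var / gene_mean), -Inf)
  dispersion <- unname(dispersion)
  gene_mean <- unname(gene_mean)

  ## z-score within equal-count bins of the gene mean
  ok <- is.finite(dispersion)
  bins <- rep(NA_integer_, length(gene_mean))
  bins[ok] <- as.integer(cut(rank(gene_mean[ok], ties.method = "first"),
                             breaks = n_bins, labels = FALSE, include.lowest = TRUE))
  scaled <- rep(-Inf, length(dispersion))
  for (b in unique(bins[ok])) {
    idx <- which(bins == b & ok)
    mu <- mean(dispersion[idx])
    sdv <- sd(dispersion[idx])
    scaled[idx] <- if (is.na(sdv) || sdv == 0) 0 else (dispersion[idx] - mu) / sdv
  }
  genes <- colnames(X) %||% sprintf("gene%d", seq_along(gene_mean))
  tibble(gene = genes, mean = gene_mean, dispersion = dispersion,
         dispersion_scaled = scaled,
         selected = gene_mean > mean_cutoff & scaled > dispersion_cutoff)
}

#' Regress covariates out of log-normalized expression and scale
#'
#' Per gene: fit least squares on the design (with intercept), subtract the
#' fitted values, and divide the residuals by their standard deviation.
#' Genes with zero residual variance map to all-zeros.
#'
#' @param log_norm Cells x genes matrix of log-transformed normalized counts.
#' @param design A [build_design()] matrix (or `NULL`: center and scale only).
#' @return Dense cells x genes matrix of scaled residuals.
#' @export
regress_scale <- function(log_norm, design = NULL) {
  X <- as_dense(log_norm)
  n <- nrow(X)
  qr_x <- design_qr(design, n)
  resid <- qr.resid(qr_x, X)
  s <- sqrt(colSums(resid^2) / (n - 1))
  tot <- sqrt(colSums(sweep(X, 2, colMeans(X))^2) / (n - 1))
  keep <- s > tot * 1e-8  # exact fits collapse to zero, not to noise
  resid[, !keep] <- 0
  resid[, keep] <- sweep(resid[, keep, drop = FALSE], 2, s[keep], "/")
  resid[, !keep] <- 0
  resid
}
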