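#' Extract a gene x gene weight matrix from a cluster GRN
#'
#' @param grn A [fit_cluster_grn()] object (retained edges only).
#' @param cluster Which cluster's network; defaults to pooling all clusters
#'   (mean weight over clusters where the edge is retained).
#' @param genes Optional gene universe for the matrix dimensions.
#' @return Matrix `W` with `W[r, g]` the weight of edge r -> g.
#' @export
grn_weight_matrix <- function(grn, cluster = NULL, genes = NULL) {
  edges <- tidy(grn)
  if (!is.null(cluster)) edges <- dplyr::filter(edges, .data$cluster == !!cluster)
  edges <- edges |>
    group_by(.data$regulator, .data$target) |>
    summarise(weight = mean(.data$weight), .groups = "drop")
  genes <- genes %||% sort(unique(c(edges$regulator, edges$target)))
  W <- matrix(0, length(genes), length(genes), dimnames = list(genes, genes))
  W[cbind(edges$regulator, edges$target)] <- edges$weight
  W
}

#' In-silico transcription-factor knockout by signal propagation
#'
#' The knocked-out genes are clamped at a shift of minus their baseline
#' expression (i.e. expression 0); at each of `depth` steps the shift vector
#' is propagated through the network (`delta <- W' delta`, with the clamp
#' re-applied), so after `depth` steps each gene carries the truncated-series
#' effect of paths of length up to `depth` from the knockout. For a stable
#' network (spectral radius < 1) the deep limit solves the linear fixed
#' point with the knockout genes held at zero expression.
#'
#' @param weights Gene x gene weight matrix (`W[r, g]` = r -> g), e.g. from
#'   [grn_weight_matrix()], or a `cluster_grn`.
#' @param baseline Cells x genes baseline expression matrix (columns must
#'   cover the network genes).
#' @param ko_genes Genes to knock out.
#' @param depth Propagation depth (default 5).
#' @param clipping `"nonneg"` (default; simulated expression floored at 0),
#'   `"none"`, or `"observed_range"` (clamped to the per-gene observed range
#'   of `baseline`).
#' @return Object of class `ko_simulation`: `delta` (cells x genes shift),
#'   `simulated` (baseline + delta, clipped), `ko_genes`, `depth`.
#' @export
simulate_ko <- function(weights, baseline, ko_genes, depth = 5,
                        clipping = c("nonneg", "none", "observed_range")) {
  clipping <- match.arg(clipping)
  if (inherits(weights, "cluster_grn")) weights <- grn_weight_matrix(weights)
  stopifnot(depth >= 1)
  B <- as_dense(baseline)
  genes <- colnames(weights)
  if (is.null(colnames(B))) colnames(B) <- genes
  missing <- setdiff(genes, colnames(B))
  if (length(missing)) abort(sprintf("Baseline lacks network gene(s): %s",
                                     paste(head(missing, 5), collapse = ", ")))
  B <- B[, genes, drop = FALSE]
  ko <- intersect(ko_genes, genes)
  if (!length(ko)) {
    warn("No knockout gene is present in the network; returning zero shifts.")
    delta <- matrix(0, nrow(B), ncol(B), dimnames = dimnames(B))
    return(structure(list(delta = delta, simulated = B, ko_genes = character(),
                          depth = depth), class = "ko_simulation"))
  }
  delta <- matrix(0, nrow(B), length(genes), dimnames = list(rownames(B), genes))
  delta[, ko] <- -B[, ko, drop = FALSE]
  for (step in seq_len(depth)) {
    delta <- delta %*% weights          # delta[g] <- sum_r W[r, g] delta[r]
    delta[, ko] <- -B[, ko, drop = FALSE]
  }
  simulated <- B + delta
  simulated <- switch(clipping,
                      none = simulated,
                      nonneg = pmax(simulated, 0),
                      observed_range = {
                        lo <- apply(B, 2, min); hi <- apply(B, 2, max)
                        pmin(pmax(simulated, rep(lo, each = nrow(B))),
                             rep(hi, each = nrow(B)))
                      })
  structure(list(delta = simulated - B, simulated = simulated,
                 ko_genes = ko, depth = depth),
            class = "ko_simulation")
}

#' @export
print.ko_simulation <- function(x, ...) {
  cat(sprintf("In-silico knockout of %s: depth %d, %d cells x %d genes\n",
              paste(x$ko_genes, collapse = ", "), x$depth,
              nrow(x$delta), ncol(x$delta)))
  invisible(x)
}

#' Compare simulated knockout shifts with experimental fold changes
#'
#' Spearman rank correlation between the per-gene mean simulated shift and
#' the per-gene experimental log2 fold change, over the shared gene universe.
#'
#' @param sim_delta Named per-gene mean simulated shift (or a
#'   `ko_simulation`, averaged over cells).
#' @param exp_log2fc Named per-gene experimental log2 fold change.
#' @return Object of class `ko_comparison`: `table` (tibble `gene`,
#'   `sim_delta`, `exp_log2fc`), `rho`, `p_value`, `n_genes`.
#' @export
compare_sim_vs_exp <- function(sim_delta, exp_log2fc) {
  if (inherits(sim_delta, "ko_simulation")) sim_delta <- colMeans(sim_delta$delta)
  genes <- intersect(names(sim_delta), names(exp_log2fc))
  if (length(genes) < 3) abort("Fewer than 3 shared genes.")
  s <- sim_delta[genes]; e <- exp_log2fc[genes]
  if (sd(s) == 0 || sd(e) == 0) {
    abort("Rank correlation undefined: one of the vectors is constant.")
  }
  ct <- suppressWarnings(stats::cor.test(s, e, method = "spearman"))
  structure(list(table = tibble(gene = genes, sim_delta = unname(s),
                                exp_log2fc = unname(e)),
                 rho = unname(ct$estimate), p_value = ct$p.value,
                 n_genes = length(genes)),
            class = "ko_comparison")
}

#' @export
print.ko_comparison <- function(x, ...) {
  cat(sprintf("Simulated vs experimental KO: Spearman rho = %.3f (p = %.3g, %d genes)\n",
              x$rho, x$p_value, x$n_genes))
  invisible(x)
}

#' @describeIn compare_sim_vs_exp One-row summary (rho, p, n).
#' @param x A `ko_comparison`.
#' @param ... Unused.
#' @export
glance.ko_comparison <- function(x, ...) {
  tibble(rho = x$rho, p_value = x$p_value, n_genes = x$n_genes)
}
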