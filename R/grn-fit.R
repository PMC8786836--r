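#' Assemble a base GRN from peak-gene links and motif hits
#'
#' A peak is linked to a gene when it overlaps the gene's TSS (link strength
#' 1) or when its co-accessibility with a TSS peak of that gene is at least
#' `coaccess_min`. The candidate regulators of a gene are the TFs whose
#' motifs hit any of its linked peaks.
#'
#' @param coaccess Co-accessibility table from [compute_coaccessibility()]
#'   (columns `peak1`, `peak2`, `correlation`).
#' @param peaks Peak table (`peak`, `chrom`, `start`, `end`).
#' @param tss Gene table (`gene`, `chrom`, `tss`).
#' @param motif_hits Binary peaks x motifs matrix (rownames = peak ids).
#' @param tf_map Tibble mapping `motif` to `tf` gene symbol.
#' @param coaccess_min Minimum co-accessibility for a distal link (default 0.5).
#' @return Object of class `base_grn`: `links` (tibble `gene`, `peak`,
#'   `type`, `coaccess`), `candidates` (tibble `target`, `regulator`), and
#'   `n_genes_without_tss_peak`.
#' @export
assemble_base_grn <- function(coaccess, peaks, tss, motif_hits, tf_map,
                              coaccess_min = 0.5) {
  require_columns(peaks, c("peak", "chrom", "start", "end"), "peaks")
  require_columns(tss, c("gene", "chrom", "tss"), "tss")
  require_columns(tf_map, c("motif", "tf"), "tf_map")
  H <- methods::as(methods::as(motif_hits, "CsparseMatrix"), "dMatrix")

  ## TSS peaks: peak overlaps the 1 bp TSS position
  pk <- to_granges(peaks)
  tss_gr <- GenomicRanges::GRanges(tss$chrom, IRanges::IRanges(tss$tss + 1, width = 1))
  hits <- GenomicRanges::findOverlaps(pk, tss_gr)
  tss_links <- tibble(gene = tss$gene[S4Vectors::subjectHits(hits)],
                      peak = peaks$peak[S4Vectors::queryHits(hits)],
                      type = "tss", coaccess = 1)
  no_tss <- setdiff(tss$gene, tss_links$gene)

  ## distal links: co-accessible (>= cutoff) with a TSS peak of the gene
  co <- dplyr::filter(as_tibble(coaccess), .data$correlation >= coaccess_min)
  both <- bind_rows(
    select(co, peak_tss = "peak1", peak_other = "peak2", "correlation"),
    select(co, peak_tss = "peak2", peak_other = "peak1", "correlation"))
  distal_links <- both |>
    dplyr::inner_join(select(tss_links, "gene", peak_tss = "peak"),
                      by = "peak_tss", relationship = "many-to-many") |>
    dplyr::transmute(gene = .data$gene, peak = .data$peak_other,
                     type = "coaccessible", coaccess = .data$correlation) |>
    dplyr::anti_join(tss_links, by = c("gene", "peak")) |>
    dplyr::distinct(.data$gene, .data$peak, .keep_all = TRUE)

  links <- bind_rows(tss_links, distal_links)

  ## candidate regulators: TFs whose motifs hit a linked peak
  hit_idx <- Matrix::which(H != 0, arr.ind = TRUE)
  peak_motifs <- tibble(peak = rownames(H)[hit_idx[, 1]],
                        motif = colnames(H)[hit_idx[, 2]])
  candidates <- links |>
    dplyr::inner_join(peak_motifs, by = "peak", relationship = "many-to-many") |>
    dplyr::inner_join(tf_map, by = "motif", relationship = "many-to-many") |>
    dplyr::distinct(target = .data$gene, regulator = .data$tf) |>
    dplyr::filter(.data$target != .data$regulator)

  structure(list(links = links, candidates = candidates,
                 n_genes_without_tss_peak = length(no_tss)),
            class = "base_grn")
}

#' @export
print.base_grn <- function(x, ...) {
  cat(sprintf("Base GRN: %d peak-gene links, %d candidate regulator-target pairs (%d gene(s) without TSS peak)\n",
              nrow(x$links), nrow(x$candidates), x$n_genes_without_tss_peak))
  invisible(x)
}

## closed-form ridge on centered data (no intercept): w = (X'X + aI)^-1 X'y
ridge_solve <- function(X, y, alpha) {
  XtX <- crossprod(X)
  diag(XtX) <- diag(XtX) + alpha
  drop(solve(XtX, crossprod(X, y)))
}

#' Fit per-cluster GRNs by bagging ridge regression
#'
#' For each cluster and each target gene, the target is regressed on its
#' base-GRN candidate regulators over that cluster's cells (columns centered
#' within the cluster, ridge penalty `alpha`, no intercept), bagged over
#' `n_bags` bootstrap resamples. The edge weight is the mean bagged
#' coefficient and the edge p-value a two-sided one-sample t-test of the
#' bagged coefficients against zero. Edges are then pruned (p <= `prune_p`,
#' |weight| > `prune_w`, regulator in the cluster's marker set when given)
#' and the surviving regulator sets are refit.
#'
#' @param expression Cells x genes matrix (imputed or raw).
#' @param clusters Per-cell cluster labels.
#' @param base A [assemble_base_grn()] object, or a tibble with `target`,
#'   `regulator` columns.
#' @param alpha Ridge penalty (default 10).
#' @param n_bags Number of bootstrap bags (default 20).
#' @param bootstrap Draw bootstrap resamples of size n with replacement; when
#'   `FALSE` (with `n_bags = 1`) the fit is the exact closed-form ridge.
#' @param prune_p,prune_w Pruning thresholds on p-value and |weight|.
#' @param markers Optional named list: per-cluster marker gene vectors; a
#'   retained edge's regulator must be a marker of that cluster.
#' @param refit Refit surviving edges after pruning (default TRUE).
#' @param seed Seed for the bootstrap.
#' @return Object of class `cluster_grn` with `edges` (tibble `cluster`,
#'   `regulator`, `target`, `weight`, `p_value`, `retained`) and the config.
#' @export
fit_cluster_grn <- function(expression, clusters, base, alpha = 10,
                            n_bags = 20, bootstrap = TRUE,
                            prune_p = 0.001, prune_w = 0.005,
                            markers = NULL, refit = TRUE, seed = 1L) {
  E <- as_dense(expression)
  cand <- if (inherits(base, "base_grn")) base$candidates else as_tibble(base)
  require_columns(cand, c("target", "regulator"), "base")
  cand <- dplyr::filter(cand, .data$target %in% colnames(E),
                        .data$regulator %in% colnames(E))
  by_target <- split(cand$regulator, cand$target)
  labs <- sort(unique(as.character(clusters)))

  fit_one <- function(Xc, yc, regs, bag_idx) {
    coefs <- vapply(bag_idx, function(idx) {
      ridge_solve(Xc[idx, , drop = FALSE], yc[idx], alpha)
    }, numeric(length(regs)))
    coefs <- matrix(coefs, nrow = length(regs))
    w <- rowMeans(coefs)
    p <- if (ncol(coefs) > 1) {
      apply(coefs, 1, function(v) {
        s <- sd(v)
        if (!is.finite(s) || s == 0) return(as.numeric(all(v == 0)))
        2 * pt(-abs(mean(v) / (s / sqrt(length(v)))), df = length(v) - 1)
      })
    } else rep(NA_real_, length(regs))
    tibble(regulator = regs, weight = w, p_value = p)
  }

  all_edges <- with_seed_local(seed, {
    out <- list()
    for (cl in labs) {
      rows <- which(as.character(clusters) == cl)
      if (length(rows) < 2) next
      Ecl <- E[rows, , drop = FALSE]
      Ecl <- sweep(Ecl, 2, colMeans(Ecl))
      n_cl <- length(rows)
      bag_idx <- if (bootstrap) {
        lapply(seq_len(n_bags), function(b) sample.int(n_cl, n_cl, replace = TRUE))
      } else rep(list(seq_len(n_cl)), n_bags)
      mk <- markers[[cl]]
      for (target in names(by_target)) {
        regs <- setdiff(by_target[[target]], target)
        if (!length(regs)) next
        fit <- fit_one(Ecl[, regs, drop = FALSE], Ecl[, target], regs, bag_idx)
        fit$retained <- (is.na(fit$p_value) | fit$p_value <= prune_p) &
          abs(fit$weight) > prune_w &
          (if (is.null(mk)) TRUE else fit$regulator %in% mk)
        if (refit && any(fit$retained) && !all(fit$retained)) {
          keep <- fit$regulator[fit$retained]
          refit_fit <- fit_one(Ecl[, keep, drop = FALSE], Ecl[, target],
                               keep, bag_idx)
          fit$weight[fit$retained] <- refit_fit$weight
          fit$p_value[fit$retained] <- refit_fit$p_value
        }
        fit$target <- target
        fit$cluster <- cl
        out[[length(out) + 1L]] <- fit
      }
    }
    bind_rows(out)
  })
  if (!nrow(all_edges)) {
    all_edges <- tibble(cluster = character(), regulator = character(),
                        target = character(), weight = numeric(),
                        p_value = numeric(), retained = logical())
  }
  structure(list(edges = select(all_edges, "cluster", "regulator", "target",
                                "weight", "p_value", "retained"),
                 config = list(alpha = alpha, n_bags = n_bags,
                               bootstrap = bootstrap, prune_p = prune_p,
                               prune_w = prune_w)),
            class = "cluster_grn")
}

#' @export
print.cluster_grn <- function(x, ...) {
  e <- x$edges
  cat(sprintf("Cluster GRN: %d edge(s) tested, %d retained, %d cluster(s)\n",
              nrow(e), sum(e$retained), length(unique(e$cluster))))
  invisible(x)
}

#' @describeIn fit_cluster_grn Edge table (optionally only retained edges).
#' @param x A `cluster_grn`.
#' @param retained_only Return only post-pruning edges.
#' @param ... Unused.
#' @export
tidy.cluster_grn <- function(x, retained_only = TRUE, ...) {
  e <- x$edges
  if (retained_only) e <- dplyr::filter(e, .data$retained)
  e
}

#' @describeIn fit_cluster_grn Per-cluster edge counts.
#' @export
glance.cluster_grn <- function(x, ...) {
  x$edges |>
    group_by(.data$cluster) |>
    summarise(n_tested = n(), n_retained = sum(.data$retained),
              .groups = "drop")
}
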