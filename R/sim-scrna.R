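#' Specification for a synthetic scRNA-seq experiment
#'
#' Describes a multi-timepoint, multi-replicate droplet scRNA experiment with
#' clustered cell states, replicate-level batch effects, cell-cycle covariates,
#' mitochondrial fractions and (optionally) planted contaminant clusters and
#' planted QC-rule violations. The defaults emulate the replicate structure of
#' a four-timepoint developmental atlas (2, 3, 3, 2 replicates) at desk scale.
#'
#' @param n_cells Total cells to simulate (before any QC).
#' @param n_genes Number of genes. Two named genes, `Hbb-bt` and `Il7`, are
#'   always appended so that gene-based QC rules and the thymus sentinel have
#'   their targets; they carry zero baseline expression unless planted.
#' @param n_clusters Number of bona fide cell-state clusters.
#' @param timepoints Named integer vector: replicate count per timepoint.
#' @param cluster_means Optional clusters x genes matrix of expected relative
#'   expression. When `NULL`, means are generated as log-normal baseline rates
#'   with `separation`-fold log-scale marker boosts per cluster.
#' @param separation Marker boost for generated cluster means, in units of the
#'   log-normal baseline standard deviation.
#' @param markers_per_cluster Number of boosted marker genes per cluster.
#' @param batch_effect_sd Standard deviation of the per-sample, per-gene
#'   log-normal batch factor (0 disables batch effects).
#' @param depth_meanlog,depth_sdlog Per-cell library-size law: log-normal
#'   parameters of the expected total UMI count.
#' @param mito_shape1,mito_shape2 Beta law for the per-cell mitochondrial
#'   UMI fraction (default mean ~3.5%).
#' @param phase_probs Probabilities of cell-cycle phases G1, S, G2M.
#' @param phase_effect Multiplicative expression boost of phase-specific genes
#'   (the first `markers_per_cluster` genes of the matrix serve as the
#'   cycling programme).
#' @param planted_contaminants List of planted contaminant clusters, each a
#'   `list(name =, n =, markers =, boost =)`; these cells get
#'   `true_cluster = name` and `is_contaminant = TRUE`.
#' @param planted_filter_counts Optional named list of exact violation counts
#'   to plant: `high_mito` (fraction > 0.07), `low_mito` (< 0.01),
#'   `high_hbb` (log-normalized Hbb-bt > 1), `low_umi` (expected depth well
#'   under 2000), `contaminant` (scattered flagged cells). When given, all
#'   remaining cells are guaranteed not to violate the corresponding rule,
#'   so ledger arithmetic is exact.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return An object of class `scrna_sim_spec`.
#' @export
scrna_sim_spec <- function(n_cells = 2000,
                           n_genes = 200,
                           n_clusters = 5,
                           timepoints = c(E9.5 = 2L, E10.5 = 3L, E11.5 = 3L, E12.5 = 2L),
                           cluster_means = NULL,
                           separation = 3,
                           markers_per_cluster = 5,
                           batch_effect_sd = 0.1,
                           depth_meanlog = log(8000),
                           depth_sdlog = 0.3,
                           mito_shape1 = 2,
                           mito_shape2 = 55,
                           phase_probs = c(G1 = 0.55, S = 0.25, G2M = 0.2),
                           phase_effect = 1.5,
                           planted_contaminants = list(),
                           planted_filter_counts = NULL,
                           seed = 1L) {
  if (any(timepoints < 1)) abort("Every timepoint needs at least one replicate.")
  planted_n <- sum(vapply(planted_contaminants, function(p) p$n, numeric(1)))
  extra <- sum(unlist(planted_filter_counts))
  if (planted_n + extra > n_cells) {
    abort("Planted cell counts exceed `n_cells`.")
  }
  structure(
    list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
         n_clusters = as.integer(n_clusters), timepoints = timepoints,
         cluster_means = cluster_means, separation = separation,
         markers_per_cluster = markers_per_cluster,
         batch_effect_sd = batch_effect_sd,
         depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
         mito_shape1 = mito_shape1, mito_shape2 = mito_shape2,
         phase_probs = phase_probs, phase_effect = phase_effect,
         planted_contaminants = planted_contaminants,
         planted_filter_counts = planted_filter_counts,
         seed = as.integer(seed)),
    class = "scrna_sim_spec")
}

#' Simulate a clustered multi-timepoint scRNA-seq count matrix
#'
#' Draws UMI counts as Poisson with per-cell size factors on top of
#' cluster-specific expected expression, per-sample batch factors and
#' cell-cycle offsets. Returns the sparse count matrix together with the cell
#' metadata the QC and batch-correction stages consume.
#'
#' @param spec An [scrna_sim_spec()].
#' @return A list of class `scrna_sim` with elements `counts` (sparse
#'   cells x genes), `cells` (tibble: `cell`, `sample`, `timepoint`,
#'   `replicate`, `true_cluster`, `cell_cycle_phase`, `mito_fraction`,
#'   `total_umi`, `is_contaminant`), and `cluster_means`.
#' @export
simulate_scrna <- function(spec) {
  stopifnot(inherits(spec, "scrna_sim_spec"))
  with_seed_local(spec$seed, {
    n <- spec$n_cells
    genes <- c(sprintf("gene%03d", seq_len(spec$n_genes)), "Hbb-bt", "Il7")
    g <- length(genes)

    ## sample assignment: cells spread evenly over timepoint x replicate
    samples <- unlist(lapply(names(spec$timepoints), function(tp) {
      paste0(tp, "_rep", seq_len(spec$timepoints[[tp]]))
    }))
    sample_of <- sample(rep_len(samples, n))
    timepoint <- sub("_rep[0-9]+$", "", sample_of)
    replicate <- as.integer(sub("^.*_rep", "", sample_of))

    ## planted sets: disjoint cell index pools, drawn before anything random
    ## about expression so counts stay reproducible under plan changes
    pool <- sample.int(n)
    take <- function(k) {
      k <- as.integer(k %||% 0L)
      if (k == 0L) return(integer(0))
      out <- pool[seq_len(k)]
      pool <<- pool[-seq_len(k)]
      out
    }
    contam_idx <- lapply(spec$planted_contaminants, function(p) take(p$n))
    pf <- spec$planted_filter_counts
    idx_high_mito <- take(pf$high_mito)
    idx_low_mito  <- take(pf$low_mito)
    idx_high_hbb  <- take(pf$high_hbb)
    idx_low_umi   <- take(pf$low_umi)
    idx_contam    <- take(pf$contaminant)

    ## cluster means
    cm <- spec$cluster_means
    if (is.null(cm)) {
      base <- rlnorm(spec$n_genes, meanlog = 0, sdlog = 1)
      cm <- matrix(rep(base, each = spec$n_clusters), spec$n_clusters, spec$n_genes)
      for (k in seq_len(spec$n_clusters)) {
        mk <- ((k - 1) * spec$markers_per_cluster + seq_len(spec$markers_per_cluster) - 1) %%
          spec$n_genes + 1
        cm[k, mk] <- cm[k, mk] * exp(spec$separation * 1)   # sdlog = 1 baseline
      }
    }
    cm <- cbind(cm, `Hbb-bt` = 0, Il7 = 0)
    colnames(cm) <- genes

    cluster <- as.character(sample.int(nrow(cm) - 0, n, replace = TRUE))
    ## contaminant clusters get their own labels and signatures
    contam_rows <- list()
    for (i in seq_along(spec$planted_contaminants)) {
      p <- spec$planted_contaminants[[i]]
      sig <- cm[1, , drop = TRUE]
      mk <- intersect(p$markers %||% character(), genes)
      sig[mk] <- sig[mk] * (p$boost %||% 20)
      contam_rows[[p$name]] <- sig
      cluster[contam_idx[[i]]] <- p$name
    }
    is_contam <- rep(FALSE, n)
    is_contam[unlist(contam_idx)] <- TRUE
    is_contam[idx_contam] <- TRUE

    ## cell cycle
    phase <- sample(names(spec$phase_probs), n, replace = TRUE, prob = spec$phase_probs)
    cycling_genes <- seq_len(min(spec$markers_per_cluster, spec$n_genes))

    ## depth: planted low-umi cells get expected depth ~1000; everyone else
    ## is truncated well above 2000 so the rule separates them cleanly
    depth <- rlnorm(n, spec$depth_meanlog, spec$depth_sdlog)
    if (length(idx_low_umi)) {
      depth <- pmax(depth, 3000)
      depth[idx_low_umi] <- runif(length(idx_low_umi), 600, 1400)
    }

    ## mitochondrial fraction: beta law, truncated away from the rule
    ## boundaries when exact planting is requested
    mito <- rbeta(n, spec$mito_shape1, spec$mito_shape2)
    if (!is.null(pf)) mito <- pmin(pmax(mito, 0.011), 0.069)
    mito[idx_high_mito] <- runif(length(idx_high_mito), 0.08, 0.20)
    mito[idx_low_mito]  <- runif(length(idx_low_mito), 0, 0.009)

    ## expected expression per cell
    rate <- matrix(0, n, g, dimnames = list(NULL, genes))
    for (lab in unique(cluster)) {
      rows <- which(cluster == lab)
      mu <- if (lab %in% names(contam_rows)) contam_rows[[lab]] else cm[as.integer(lab), ]
      rate[rows, ] <- matrix(rep(mu, each = length(rows)), length(rows), g)
    }
    if (spec$batch_effect_sd > 0) {
      for (s in samples) {
        rows <- which(sample_of == s)
        bf <- rlnorm(g, 0, spec$batch_effect_sd)
        rate[rows, ] <- sweep(rate[rows, , drop = FALSE], 2, bf, "*")
      }
    }
    boost <- rep(1, n)
    boost[phase != "G1"] <- spec$phase_effect
    rate[, cycling_genes] <- rate[, cycling_genes] * boost

    rs <- rowSums(rate)
    rs[rs == 0] <- 1
    lambda <- rate * (depth / rs)
    counts <- matrix(rpois(n * g, lambda), n, g, dimnames = list(NULL, genes))

    ## exact Hbb-bt planting: zero everywhere, then enough counts that the
    ## log-normalized value clears 1 for the planted cells
    counts[, "Hbb-bt"] <- 0L
    if (length(idx_high_hbb)) {
      tot <- rowSums(counts[idx_high_hbb, , drop = FALSE])
      counts[idx_high_hbb, "Hbb-bt"] <- pmax(1L, ceiling(2 * tot / 1e4))
    }

    cell_id <- sprintf("cell%06d", seq_len(n))
    rownames(counts) <- cell_id
    cells <- tibble(
      cell = cell_id, sample = sample_of, timepoint = timepoint,
      replicate = replicate, true_cluster = cluster,
      cell_cycle_phase = phase, mito_fraction = mito,
      total_umi = rowSums(counts), is_contaminant = is_contam)

    structure(list(counts = methods::as(counts, "CsparseMatrix"),
                   cells = cells, cluster_means = cm, spec = spec),
              class = "scrna_sim")
  })
}
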