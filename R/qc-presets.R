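# Replay presets for the published QC accounting of the pharyngeal-endoderm
# atlas datasets. The printed exclusion structure (contaminant-cluster sizes,
# per-rule removal counts, per-sample cell numbers) is treated as input data;
# the generators plant exactly that structure into synthetic metadata so the
# ledger machinery can reproduce the published cell counts end to end.

#' Simulation spec replaying the scRNA atlas QC structure
#'
#' 57,850 cells over four timepoints (2/3/3/2 replicates), five planted
#' contaminant clusters (459, 79, 381, 247, 231 cells), and exactly 2122
#' high-mitochondrial, 270 low-mitochondrial and 17 haemoglobin-positive
#' cells among the rest — the exclusion structure whose ledger telescopes to
#' 54,044 retained cells.
#'
#' @param seed Integer seed.
#' @param n_genes Number of background genes (the QC replay only needs the
#'   named QC genes; keep this small for speed).
#' @return An [scrna_sim_spec()].
#' @export
atlas_qc_spec <- function(seed = 1L, n_genes = 40) {
  scrna_sim_spec(
    n_cells = 57850, n_genes = n_genes, n_clusters = 6,
    timepoints = c(E9.5 = 2L, E10.5 = 3L, E11.5 = 3L, E12.5 = 2L),
    planted_contaminants = list(
      list(name = "33", n = 459, markers = "gene001", boost = 30),
      list(name = "41", n = 79,  markers = "gene002", boost = 30),
      list(name = "36", n = 381, markers = "gene003", boost = 30),
      list(name = "38", n = 247, markers = "gene002", boost = 30),
      list(name = "39", n = 231, markers = "gene004", boost = 30)),
    planted_filter_counts = list(high_mito = 2122, low_mito = 270,
                                 high_hbb = 17),
    seed = seed)
}

#' Atlas-style cell filter rules
#'
#' Strict "over 7%" / "under 1%" mitochondrial-fraction rules and the
#' log2-normalized haemoglobin rule (`Hbb-bt` over 1).
#'
#' @return List of [qc_rule()]s, in application order.
#' @export
atlas_qc_rules <- function() {
  list(qc_rule("mito fraction over 7%", "mito_fraction", "greater_than", 0.07),
       qc_rule("mito fraction under 1%", "mito_fraction", "less_than", 0.01),
       qc_rule("log-normalized Hbb-bt over 1", "lognorm_Hbb-bt",
               "greater_than", 1))
}

#' Excluded atlas cluster labels
#' @return Character vector of contaminant cluster labels, in ledger order.
#' @export
atlas_excluded_clusters <- function() c("33", "41", "36", "38", "39")

#' Simulation spec replaying the knockout-experiment QC structure
#'
#' 29,276 cells across four E12.5 samples (two genotypes, two replicates
#' each), six planted removable clusters (3362, 1150, 318, 207, 132, 37
#' cells), then exactly 2121 low-depth (< 2000 UMI) cells and 45 scattered
#' contaminants among the remainder — telescoping to 21,904 retained cells.
#'
#' @inheritParams atlas_qc_spec
#' @return An [scrna_sim_spec()].
#' @export
ko_qc_spec <- function(seed = 1L, n_genes = 40) {
  scrna_sim_spec(
    n_cells = 29276, n_genes = n_genes, n_clusters = 6,
    timepoints = c(E12.5het = 2L, E12.5homo = 2L),
    planted_contaminants = list(
      list(name = "0",  n = 3362, markers = "gene001", boost = 25),
      list(name = "10", n = 1150, markers = "gene002", boost = 25),
      list(name = "24", n = 318,  markers = "gene003", boost = 25),
      list(name = "27", n = 207,  markers = "gene004", boost = 25),
      list(name = "28", n = 132,  markers = "gene005", boost = 25),
      list(name = "30", n = 37,   markers = "gene001", boost = 25)),
    planted_filter_counts = list(low_umi = 2121, contaminant = 45),
    seed = seed)
}

#' Knockout-style cell filter rules (depth, then contaminant flag)
#' @return List of [qc_rule()]s, in application order.
#' @export
ko_qc_rules <- function() {
  list(qc_rule("under 2000 UMIs", "total_umi", "less_than", 2000),
       qc_rule("classified contaminant", "is_contaminant", "at_least", 1))
}

#' Excluded knockout-experiment cluster labels
#' @return Character vector, in ledger order.
#' @export
ko_excluded_clusters <- function() c("0", "10", "24", "27", "28", "30")

## published per-sample tables -------------------------------------------

#' Published per-sample cell counts of the scRNA atlas after QC
#'
#' @return Tibble: `sample`, `timepoint`, `cells` (summing to 54,044).
#' @export
atlas_sample_counts <- function() {
  tibble(
    sample = c("E9.5_rep1", "E9.5_rep2", "E10.5_rep1", "E10.5_rep2",
               "E10.5_rep3", "E11.5_rep1", "E11.5_rep2", "E11.5_rep3",
               "E12.5_rep1", "E12.5_rep2"),
    timepoint = rep(c("E9.5", "E10.5", "E11.5", "E12.5"), c(2, 3, 3, 2)),
    cells = c(5734, 7611, 4743, 4129, 4248, 5385, 3141, 7967, 4885, 6201))
}

#' Per-sample scATAC metadata replaying the doublet-quota stage
#'
#' Four samples with the published post-depth-filter sizes (4320, 1273,
#' 3576, 4784; total 13,953) and random doublet-enrichment scores; applying
#' [apply_doublet_quota()] with the default divisor removes 186/16/127/228
#' cells, leaving 13,396.
#'
#' @param seed Integer seed for the enrichment scores.
#' @return Tibble: `cell`, `sample`, `doublet_enrichment`.
#' @export
atac_doublet_cells <- function(seed = 1L) {
  sizes <- c(E11.5_rep1 = 4320, E11.5_rep2 = 1273,
             E12.5_rep1 = 3576, E12.5_rep2 = 4784)
  with_seed_local(seed, {
    tibble(cell = sprintf("atac%05d", seq_len(sum(sizes))),
           sample = rep(names(sizes), sizes),
           doublet_enrichment = runif(sum(sizes)))
  })
}

#' Post-doublet scATAC metadata replaying the cluster-removal stage
#'
#' 13,396 cells across four samples; the cells that the published analysis
#' removed as 12 non-endodermal/doublet clusters (886, 182, 636 and 802 per
#' sample, 2506 in total) carry those cluster labels, everyone else a kept
#' label. Excluding the 12 clusters leaves the published per-sample counts
#' 3248 / 1075 / 2813 / 3754 (total 10,890).
#'
#' @param seed Integer seed (cluster labels are spread round-robin).
#' @return Tibble: `cell`, `sample`, `timepoint`, `cluster`.
#' @export
atac_cluster_cells <- function(seed = 1L) {
  pre <- c(E11.5_rep1 = 4320 - 186, E11.5_rep2 = 1273 - 16,
           E12.5_rep1 = 3576 - 127, E12.5_rep2 = 4784 - 228)
  post <- c(E11.5_rep1 = 3248, E11.5_rep2 = 1075,
            E12.5_rep1 = 2813, E12.5_rep2 = 3754)
  removed_clusters <- atac_excluded_clusters()
  with_seed_local(seed, {
    out <- lapply(names(pre), function(s) {
      n_rm <- pre[[s]] - post[[s]]
      cl <- c(rep_len(removed_clusters, n_rm),
              rep_len(sprintf("K%02d", 1:10), post[[s]]))
      tibble(sample = s, cluster = sample(cl))
    })
    out <- bind_rows(out)
    out$cell <- sprintf("atac%05d", seq_len(nrow(out)))
    out$timepoint <- sub("_rep[0-9]+$", "", out$sample)
    out[, c("cell", "sample", "timepoint", "cluster")]
  })
}

#' Removed scATAC cluster labels (7 non-endodermal + 5 doublet)
#' @return Character vector, in ledger order.
#' @export
atac_excluded_clusters <- function() {
  c("C40", "C42", "C1", "C37", "C41", "C28", "C36",
    "C30", "C11", "C31", "C29", "C27")
}
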