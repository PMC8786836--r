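#' Simulate a null cluster-abundance dataset for CI calibration
#'
#' Generates replicate cell populations in which one focal cluster occupies
#' the same expected fraction in both genotypes (a true log fold change of
#' zero), with hard label assignments wrapped as a [classify_knn()]-style
#' projection result. Used to check the calibration of [abundance_ci()]
#' confidence intervals: at the default design (64 replicates per genotype
#' over 2 batches, ~400 cells each) the asymptotic Wald interval is in its
#' valid regime.
#'
#' @param n_rep_per_genotype Replicates per genotype (default 64).
#' @param mean_total Expected cells per replicate.
#' @param cluster_fraction Expected focal-cluster fraction in both genotypes.
#' @param k Neighbour count stored on the projection result.
#' @param seed Integer seed.
#' @return List with `result` (a `projection_result` with clusters `X` and
#'   `other`) and `cells` (tibble `cell`, `replicate`, `genotype`, `batch`).
#' @export
simulate_abundance_null <- function(n_rep_per_genotype = 64, mean_total = 400,
                                    cluster_fraction = 0.25, k = 50,
                                    seed = 1L) {
  with_seed_local(seed, {
    n_rep <- 2 * n_rep_per_genotype
    reps <- sprintf("r%02d", seq_len(n_rep))
    genotype <- rep(c("het", "ko"), each = n_rep_per_genotype)
    batch <- rep_len(c("d1", "d2"), n_rep)
    total <- rpois(n_rep, mean_total)
    ## focal-cluster counts Poisson with rate proportional to replicate size:
    ## a genuinely null genotype effect under the fitted model
    n_x <- pmin(rpois(n_rep, cluster_fraction * total), total)
    cells <- bind_rows(lapply(seq_len(n_rep), function(i) {
      n <- max(total[i], 1)
      tibble(cell = sprintf("%s_c%04d", reps[i], seq_len(n)),
             replicate = reps[i], genotype = genotype[i], batch = batch[i],
             lab = rep(c("X", "other"), c(n_x[i], n - n_x[i])))
    }))
    prob <- matrix(0, nrow(cells), 2, dimnames = list(cells$cell, c("X", "other")))
    prob[cbind(seq_len(nrow(cells)), ifelse(cells$lab == "X", 1L, 2L))] <- 1
    result <- structure(
      list(cells = tibble(cell = cells$cell, label = cells$lab),
           prob = prob, k = k),
      class = "projection_result")
    list(result = result,
         cells = cells[, c("cell", "replicate", "genotype", "batch")])
  })
}
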