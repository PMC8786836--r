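#' Construct a ground-truth linear gene regulatory network
#'
#' Builds a sparse signed TF -> target weight matrix with no self-edges,
#' rescaled (when `stable = TRUE`) so that the spectral radius is below 1 and
#' the linear structural model has a fixed point.
#'
#' @param n_genes Number of genes in the network universe.
#' @param n_tfs Number of regulator genes (the first `n_tfs` genes).
#' @param targets_per_tf Expected number of targets per regulator.
#' @param weight_range Range of absolute edge weights.
#' @param prob_negative Probability that an edge is repressive.
#' @param baseline_meanlog,baseline_sdlog Log-normal law of per-gene baseline
#'   expression.
#' @param noise_sd Standard deviation of the per-cell structural noise.
#' @param stable Rescale weights so the spectral radius is < 1.
#' @param seed Integer seed.
#' @return A list of class `grn_truth`: `edges` (tibble regulator/target/
#'   weight), `W` (genes x genes weight matrix, `W[r, g]` = weight of r -> g),
#'   `baseline`, `noise_sd`, `tfs`.
#' @export
simulate_grn_truth <- function(n_genes = 30, n_tfs = 6, targets_per_tf = 4,
                               weight_range = c(0.3, 0.8), prob_negative = 0.3,
                               baseline_meanlog = log(5), baseline_sdlog = 0.3,
                               noise_sd = 0.5, stable = TRUE, seed = 1L) {
  with_seed_local(seed, {
    genes <- sprintf("g%03d", seq_len(n_genes))
    tfs <- genes[seq_len(n_tfs)]
    W <- matrix(0, n_genes, n_genes, dimnames = list(genes, genes))
    edges <- list()
    for (r in seq_len(n_tfs)) {
      k <- max(1L, rpois(1, targets_per_tf))
      tg <- sample(setdiff(seq_len(n_genes), r), min(k, n_genes - 1))
      wts <- runif(length(tg), weight_range[1], weight_range[2]) *
        ifelse(runif(length(tg)) < prob_negative, -1, 1)
      W[r, tg] <- wts
    }
    if (stable) {
      rho <- max(Mod(eigen(W, only.values = TRUE)$values))
      if (rho >= 0.95) W <- W * (0.8 / rho)
    }
    nz <- which(W != 0, arr.ind = TRUE)
    edges <- tibble(regulator = genes[nz[, 1]], target = genes[nz[, 2]],
                    weight = W[nz])
    structure(list(edges = edges, W = W,
                   baseline = setNames(rlnorm(n_genes, baseline_meanlog,
                                              baseline_sdlog), genes),
                   noise_sd = noise_sd, tfs = tfs),
              class = "grn_truth")
  })
}

#' Simulate expression from a ground-truth linear GRN
#'
#' Draws per-cell expression at the fixed point of the linear structural
#' model `x = baseline + W' (x - baseline) + e`, i.e.
#' `x = baseline + (I - W')^{-1} e`. In `"baseline_jitter"` mode an extra
#' per-cell scalar jitter (shared by all genes) is injected through the same
#' propagator, so regulator-target correlations exist even at `noise_sd = 0`.
#'
#' @param truth A [simulate_grn_truth()] object.
#' @param n_cells Number of cells to draw.
#' @param seed Integer seed.
#' @param mode `"noise"` (structural noise only) or `"baseline_jitter"`.
#' @param jitter_sd Standard deviation of the jitter term.
#' @return Dense `n_cells` x genes expression matrix (continuous; floor at 0
#'   and round to convert to counts).
#' @export
simulate_grn_expression <- function(truth, n_cells, seed = 1L,
                                    mode = c("noise", "baseline_jitter"),
                                    jitter_sd = 1) {
  stopifnot(inherits(truth, "grn_truth"))
  mode <- match.arg(mode)
  W <- truth$W
  rho <- max(Mod(eigen(W, only.values = TRUE)$values))
  if (rho >= 1) abort("Unstable truth network (spectral radius >= 1).")
  n_genes <- ncol(W)
  with_seed_local(seed, {
    eps <- matrix(rnorm(n_cells * n_genes, 0, truth$noise_sd), n_cells, n_genes)
    if (mode == "baseline_jitter") {
      ## a per-cell scalar jitter shared by all genes, so regulator-target
      ## correlations are exact even with no structural noise
      eps <- eps + matrix(rnorm(n_cells, 0, jitter_sd), n_cells, n_genes)
    }
    ## x - b solves (I - W') d = e  =>  d = e (I - W)^{-1} row-wise
    d <- eps %*% solve(diag(n_genes) - W)
    x <- sweep(d, 2, truth$baseline, "+")
    colnames(x) <- colnames(W)
    rownames(x) <- sprintf("cell%05d", seq_len(n_cells))
    x
  })
}

#' Simulate a one-dimensional developmental trajectory
#'
#' A trivial pseudotime generator: cells are ordered 1..n, a planted set of
#' dynamic genes changes monotonically (log-linear) along the ordering, and
#' the remaining genes are flat. Used to exercise pseudotime binning, the
#' dynamic-gene screen and rank-correlation staging.
#'
#' @param n_cells,n_genes Dataset dimensions.
#' @param n_dynamic Number of planted dynamic genes.
#' @param fold_change Log2 fold change of a dynamic gene from start to end.
#' @param depth Expected per-cell total count.
#' @param seed Integer seed.
#' @return A list of class `trajectory_sim`: `counts` (cells x genes),
#'   `pseudotime` (per-cell rank), `dynamic_genes`.
#' @export
simulate_trajectory <- function(n_cells = 400, n_genes = 200, n_dynamic = 40,
                                fold_change = 3, depth = 2000, seed = 1L) {
  with_seed_local(seed, {
    genes <- sprintf("g%03d", seq_len(n_genes))
    dyn <- sample(genes, n_dynamic)
    t <- seq(0, 1, length.out = n_cells)
    base <- rlnorm(n_genes, 0, 0.5)
    mu <- matrix(rep(base, each = n_cells), n_cells, n_genes,
                 dimnames = list(sprintf("cell%05d", seq_len(n_cells)), genes))
    dir <- sample(c(-1, 1), n_dynamic, replace = TRUE)
    for (i in seq_len(n_dynamic)) {
      mu[, dyn[i]] <- mu[, dyn[i]] * 2^(fold_change * (if (dir[i] > 0) t else 1 - t))
    }
    lam <- mu * (depth / rowSums(mu))
    counts <- matrix(rpois(length(lam), lam), n_cells, n_genes,
                     dimnames = dimnames(mu))
    structure(list(counts = methods::as(counts, "CsparseMatrix"),
                   pseudotime = seq_len(n_cells), dynamic_genes = sort(dyn)),
              class = "trajectory_sim")
  })
}
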