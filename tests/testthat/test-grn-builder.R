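# Aggregates, co-accessibility, base GRN, bagging ridge, network stats,
# regulator ranking.

test_that("aggregates respect the overlap cutoff and are seed-deterministic", {
  withr::with_seed(55, {
    coords <- matrix(rnorm(600 * 5), 600, 5)
  })
  agg <- sample_aggregates(coords, k = 40, n_iterations = 120,
                           overlap_cutoff = 0.6, seed = 3)
  expect_lt(length(agg), 120)
  ov <- sapply(agg, function(a) sapply(agg, function(b) length(intersect(a, b)) / 40))
  diag(ov) <- 0
  expect_lte(max(ov), 0.6)
  agg2 <- sample_aggregates(coords, k = 40, n_iterations = 120,
                            overlap_cutoff = 0.6, seed = 3)
  expect_identical(agg, agg2)
  # k = 1 with any cutoff < 1: aggregates are distinct single cells
  singles <- sample_aggregates(coords, k = 1, n_iterations = 50,
                               overlap_cutoff = 0.5, seed = 4)
  expect_equal(anyDuplicated(unlist(singles)), 0)
  expect_error(sample_aggregates(coords[1:10, ], k = 40), "Fewer cells")
})

test_that("identical candidate aggregates are rejected at any cutoff below 1", {
  coords <- matrix(rep(c(0, 10), each = 60), 120, 2)  # two tight blobs
  agg <- sample_aggregates(coords, k = 60, n_iterations = 200,
                           overlap_cutoff = 0.99, seed = 1)
  # every candidate equals one of the two blobs; only 2 can be accepted
  expect_lte(length(agg), 2)
})

test_that("co-accessibility: perfect correlation retained, cross-chromosome never paired", {
  peaks <- tibble::tibble(peak = sprintf("p%d", 1:4),
                          chrom = c("chr1", "chr1", "chr2", "chr2"),
                          start = c(0, 1000, 0, 500000), end = c(501, 1501, 501, 500501))
  withr::with_seed(6, {
    base <- rpois(40, 20)
    X <- cbind(p1 = base, p2 = base,            # identical counts: r = 1
               p3 = rpois(40, 20), p4 = rpois(40, 20))
  })
  agg <- lapply(1:40, identity)  # one cell per aggregate
  out <- compute_coaccessibility(X, agg, peaks, fdr_max = 0.05,
                                 variability_min = 0, corr_min = 0.5,
                                 return_all = TRUE)
  expect_setequal(paste(out$peak1, out$peak2), "p1 p2")  # same-chrom, in range
  expect_equal(out$correlation[1], 1)
  expect_true(out$retained[1])
  # chr2 pair is beyond max_distance; chr1-chr2 pairs never tested
  expect_false(any(grepl("p3|p4", paste(out$peak1, out$peak2))))
})

test_that("independent-noise peaks rarely reach the correlation cutoff", {
  withr::with_seed(91, {
    n_agg <- 200
    peaks <- tibble::tibble(peak = sprintf("p%02d", 1:30), chrom = "chr1",
                            start = seq(0, by = 2000, length.out = 30))
    peaks$end <- peaks$start + 501
    X <- matrix(rpois(400 * 30, 5), 400, 30,
                dimnames = list(NULL, peaks$peak))
    agg <- lapply(1:n_agg, function(i) sample.int(400, 20))
    out <- compute_coaccessibility(X, agg, peaks, return_all = TRUE)
    expect_gte(mean(out$correlation < 0.5, na.rm = TRUE), 0.99)
    # BH monotonicity: fdr ordering follows p ordering
    ord <- order(out$p_value)
    expect_true(all(diff(out$fdr[ord]) >= -1e-12))
  })
})

test_that("co-accessibility is symmetric in peak order", {
  withr::with_seed(8, {
    peaks <- tibble::tibble(peak = sprintf("p%d", 1:6), chrom = "chr1",
                            start = seq(0, by = 1000, length.out = 6))
    peaks$end <- peaks$start + 501
    X <- matrix(rpois(200 * 6, 10), 200, 6, dimnames = list(NULL, peaks$peak))
    agg <- lapply(1:50, function(i) sample.int(200, 10))
    a <- compute_coaccessibility(X, agg, peaks, return_all = TRUE)
    perm <- 6:1
    b <- compute_coaccessibility(X[, perm], agg, peaks[perm, ], return_all = TRUE)
    key <- function(d) {
      k <- paste(pmin(d$peak1, d$peak2), pmax(d$peak1, d$peak2))
      d <- d[order(k), ]; d$key <- sort(k); d
    }
    expect_equal(key(a)$correlation, key(b)$correlation, tolerance = 1e-12)
  })
})

test_that("base GRN links TSS peaks, thresholds co-accessibility at 0.5, and maps motifs", {
  peaks <- tibble::tibble(peak = c("pk_tss", "pk_hi", "pk_lo"),
                          chrom = "chr1",
                          start = c(9800, 50000, 80000),
                          end = c(10301, 50501, 80501))
  tss <- tibble::tibble(gene = "gA", chrom = "chr1", tss = 10000)
  coaccess <- tibble::tibble(peak1 = c("pk_tss", "pk_tss"),
                             peak2 = c("pk_hi", "pk_lo"),
                             correlation = c(0.6, 0.4))
  H <- matrix(0, 3, 2, dimnames = list(peaks$peak, c("m1", "m2")))
  H["pk_tss", "m1"] <- 1   # TF1 at the promoter
  H["pk_hi", "m2"] <- 1    # TF2 at the linked distal peak
  H["pk_lo", "m2"] <- 1    # on an unlinked peak: must not create an edge
  tf_map <- tibble::tibble(motif = c("m1", "m2"), tf = c("TF1", "TF2"))
  base <- assemble_base_grn(coaccess, peaks, tss, H, tf_map)
  expect_setequal(base$links$peak, c("pk_tss", "pk_hi"))
  expect_setequal(base$candidates$regulator, c("TF1", "TF2"))
  expect_true(all(base$candidates$target == "gA"))
})

test_that("hand-enumerated toy base GRN matches", {
  # 3 genes, 5 peaks, 2 motifs
  peaks <- tibble::tibble(peak = sprintf("p%d", 1:5), chrom = "chr1",
                          start = c(1000, 3000, 5000, 7000, 9000))
  peaks$end <- peaks$start + 501
  tss <- tibble::tibble(gene = c("gA", "gB", "gC"), chrom = "chr1",
                        tss = c(1200, 5200, 9200))
  coaccess <- tibble::tibble(peak1 = c("p1", "p2", "p4"),
                             peak2 = c("p2", "p3", "p5"),
                             correlation = c(0.7, 0.55, 0.9))
  H <- matrix(0, 5, 2, dimnames = list(peaks$peak, c("m1", "m2")))
  H["p2", "m1"] <- 1; H["p4", "m2"] <- 1; H["p5", "m1"] <- 1
  tf_map <- tibble::tibble(motif = c("m1", "m2"), tf = c("TF1", "TF2"))
  base <- assemble_base_grn(coaccess, peaks, tss, H, tf_map)
  # by hand: gA <- {p1 (tss), p2 (0.7)}; gB <- {p3 (tss), p2 (0.55)};
  #          gC <- {p5 (tss), p4 (0.9)}
  # motifs: p2 -> m1/TF1 (gA, gB); p4 -> m2/TF2 (gC); p5 -> m1/TF1 (gC)
  got <- dplyr::arrange(base$candidates, target, regulator)
  expect_equal(got,
               tibble::tibble(target = c("gA", "gB", "gC", "gC"),
                              regulator = c("TF1", "TF1", "TF1", "TF2")))
})

test_that("single-regulator ridge matches the closed form and the SVD oracle", {
  # centered x with sum of squares exactly 100, y = 2x, alpha = 10:
  # w = sum(xy) / (sum(x^2) + alpha) = 200 / 110
  withr::with_seed(60, x <- rnorm(100))
  x <- x - mean(x)
  x <- x / sqrt(sum(x^2)) * 10                      # sum(x^2) = 100
  y <- 2 * x
  expr <- cbind(reg = x, tgt = y)
  grn <- fit_cluster_grn(expr, rep("c", 100),
                         tibble::tibble(target = "tgt", regulator = "reg"),
                         alpha = 10, n_bags = 1, bootstrap = FALSE,
                         prune_w = 0)
  expect_equal(grn$edges$weight, 200 / 110, tolerance = 1e-10)
  expect_equal(grn$edges$weight,
               oracle_ridge_svd(matrix(x), y, 10), tolerance = 1e-10)
})

test_that("multi-regulator closed-form agreement without bagging", {
  withr::with_seed(61, {
    n <- 150
    X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, sprintf("r%d", 1:4)))
    y <- X %*% c(1, -0.5, 0, 0.3) + rnorm(n, 0, 0.2)
    expr <- cbind(X, tgt = as.numeric(y))
    cand <- tibble::tibble(target = "tgt", regulator = sprintf("r%d", 1:4))
    grn <- fit_cluster_grn(expr, rep("c", n), cand, alpha = 10, n_bags = 1,
                           bootstrap = FALSE, prune_w = 0)
    Xc <- scale(X, scale = FALSE); yc <- y - mean(y)
    expect_equal(grn$edges$weight[match(sprintf("r%d", 1:4), grn$edges$regulator)],
                 oracle_ridge_svd(Xc, yc, 10), tolerance = 1e-8)
  })
})

test_that("noise targets are mostly pruned and pruning is monotone in its thresholds", {
  withr::with_seed(62, {
    # a pure-noise target against many candidate regulators: the bag-level
    # t-test admits a null edge with probability well below 1/2 (see the
    # methods vignette for the calibration of this filter), so the retained
    # fraction must sit clearly under 0.5
    n <- 300
    expr <- matrix(rnorm(n * 41), n, 41,
                   dimnames = list(NULL, c(sprintf("r%02d", 1:40), "tgt")))
    cand <- tibble::tibble(target = "tgt", regulator = sprintf("r%02d", 1:40))
    grn <- fit_cluster_grn(expr, rep("c", n), cand, seed = 9)
    expect_lt(mean(grn$edges$retained), 0.5)

    truth <- simulate_grn_truth(n_genes = 15, n_tfs = 4, seed = 63)
    sexpr <- simulate_grn_expression(truth, 400, seed = 64)
    cand2 <- tibble::tibble(target = truth$edges$target,
                            regulator = truth$edges$regulator)
    loose <- fit_cluster_grn(sexpr, rep("c", 400), cand2, prune_p = 0.01,
                             prune_w = 0.001, seed = 65)
    tight <- fit_cluster_grn(sexpr, rep("c", 400), cand2, prune_p = 0.001,
                             prune_w = 0.01, seed = 65)
    loose_edges <- paste(tidy(loose)$regulator, tidy(loose)$target)
    tight_edges <- paste(tidy(tight)$regulator, tidy(tight)$target)
    expect_true(all(tight_edges %in% loose_edges))
  })
})

test_that("marker-set restriction drops non-marker regulators", {
  withr::with_seed(66, {
    truth <- simulate_grn_truth(n_genes = 12, n_tfs = 3, seed = 66)
    expr <- simulate_grn_expression(truth, 300, seed = 67)
    cand <- tibble::tibble(target = truth$edges$target,
                           regulator = truth$edges$regulator)
    mk <- list(c = truth$tfs[1])
    grn <- fit_cluster_grn(expr, rep("c", 300), cand, markers = mk, seed = 68)
    expect_true(all(tidy(grn)$regulator == truth$tfs[1]))
  })
})

test_that("betweenness and outdegree match exhaustive path enumeration", {
  # directed chain: only the middle node carries a shortest path
  chain <- tibble::tibble(regulator = c("A", "B"), target = c("B", "C"))
  stats <- network_stats(chain)
  expect_equal(stats$betweenness[stats$gene == "B"], 1)
  expect_equal(stats$betweenness[stats$gene %in% c("A", "C")], c(0, 0))
  # star hub
  star <- tibble::tibble(regulator = "H", target = sprintf("t%d", 1:5))
  expect_equal(network_stats(star)$outdegree[1], 5)
  # random digraphs vs brute force
  withr::with_seed(71, {
    for (i in 1:4) {
      nodes <- sprintf("n%02d", 1:9)
      edges <- tidyr::expand_grid(regulator = nodes, target = nodes) |>
        dplyr::filter(regulator != target) |>
        dplyr::slice_sample(n = 14)
      stats <- network_stats(edges)
      oracle <- oracle_betweenness(edges, nodes)
      # nodes touching no edge are not part of the network; they carry 0
      expect_true(all(oracle[setdiff(nodes, stats$gene)] == 0))
      present <- stats$gene
      expect_equal(setNames(stats$betweenness, stats$gene)[present],
                   oracle[present], tolerance = 1e-10)
    }
  })
})

test_that("regulator ranking orders by focus intersection and drops light edges", {
  edges <- tibble::tibble(
    regulator = c(rep("R1", 5), rep("R2", 3), rep("R3", 2), "R4"),
    target = c(sprintf("f%d", 1:5), sprintf("f%d", 1:3), "f1", "x1", "x2"),
    weight = c(rep(0.5, 10), 0.001))
  focus <- sprintf("f%d", 1:5)
  rk <- rank_regulators(edges, focus, top_n = 3, resolution = 1)
  expect_equal(rk$ranking$regulator[1:3], c("R1", "R2", "R3"))
  expect_equal(rk$ranking$n_focus_targets[1:3], c(5, 3, 1))
  # R4's only edge is below the weight cutoff: no focus targets -> last
  expect_false("R4" %in% rk$ranking$regulator)
  expect_equal(nrow(rk$communities), 3)
})

test_that("subnetwork activity is zero where member genes are silent", {
  edges <- tibble::tibble(regulator = c("A", "B"), target = c("B", "A"),
                          weight = 1)
  expr <- cbind(A = c(1, 1, 0, 0), B = c(2, 2, 0, 0))
  clusters <- c("k1", "k1", "k2", "k2")
  rk <- rank_regulators(edges, focus_genes = c("A", "B"), top_n = 2,
                        expression = expr, clusters = clusters)
  act <- rk$activity
  expect_equal(act$activity[act$cluster == "k2"], rep(0, sum(act$cluster == "k2")))
})
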