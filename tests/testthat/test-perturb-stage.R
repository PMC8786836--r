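# KO propagation, sim-vs-experiment comparison, projection/classification,
# abundance inference, pseudotime staging.

chain_w <- function() {
  W <- matrix(0, 3, 3, dimnames = rep(list(c("A", "B", "C")), 2))
  W["A", "B"] <- 0.5; W["B", "C"] <- 0.5
  W
}

test_that("KO propagation: chain, cycle, no-outgoing-edges, and clamping", {
  base <- matrix(1, 2, 3, dimnames = list(NULL, c("A", "B", "C")))
  ko <- simulate_ko(chain_w(), base, "A", depth = 5, clipping = "none")
  expect_equal(unname(ko$delta[1, ]), c(-1, -0.5, -0.25))
  # depth 2 already suffices for a depth-2 chain
  ko2 <- simulate_ko(chain_w(), base, "A", depth = 2, clipping = "none")
  expect_equal(ko$delta, ko2$delta)

  # gene with no outgoing edges: only the KO gene shifts
  ko_c <- simulate_ko(chain_w(), base, "C", depth = 5, clipping = "none")
  expect_equal(unname(ko_c$delta[1, ]), c(0, 0, -1))

  # 2-cycle: truncated geometric series via the block-matrix oracle
  W <- matrix(0, 2, 2, dimnames = rep(list(c("A", "B")), 2))
  W["A", "B"] <- 0.5; W["B", "A"] <- 0.5
  b2 <- matrix(c(1, 1), 1, dimnames = list(NULL, c("A", "B")))
  ko_cyc <- simulate_ko(W, b2, "A", depth = 5, clipping = "none")
  expect_equal(unname(ko_cyc$delta[1, ]),
               unname(oracle_ko_series(W, c(A = 1, B = 1), "A", 5)))
})

test_that("depth-5 propagation equals the truncated series oracle on random stable networks", {
  withr::with_seed(81, {
    for (i in 1:5) {
      truth <- simulate_grn_truth(n_genes = 10, n_tfs = 4, seed = 81 + i)
      b <- matrix(truth$baseline, 1, dimnames = list(NULL, names(truth$baseline)))
      ko_gene <- truth$tfs[1]
      got <- simulate_ko(truth$W, b, ko_gene, depth = 5, clipping = "none")
      expect_equal(got$delta[1, ],
                   oracle_ko_series(truth$W, truth$baseline, ko_gene, 5),
                   tolerance = 1e-12)
    }
  })
})

test_that("deep propagation converges to the analytic clamped fixed point", {
  truth <- simulate_grn_truth(n_genes = 12, n_tfs = 5, seed = 83)
  b <- matrix(truth$baseline, 1, dimnames = list(NULL, names(truth$baseline)))
  got <- simulate_ko(truth$W, b, truth$tfs[2], depth = 200, clipping = "none")
  expect_equal(got$delta[1, ],
               oracle_ko_limit(truth$W, truth$baseline, truth$tfs[2]),
               tolerance = 1e-10)
})

test_that("clipping floors simulated expression at zero; missing KO gene warns", {
  W <- chain_w(); W["A", "B"] <- 2    # strong edge so B would go negative
  base <- matrix(c(5, 1, 1), 1, dimnames = list(NULL, c("A", "B", "C")))
  ko <- simulate_ko(W, base, "A", depth = 3, clipping = "nonneg")
  expect_true(all(ko$simulated >= 0))
  expect_warning(z <- simulate_ko(chain_w(), base, "Zzz"), "No knockout gene")
  expect_true(all(z$delta == 0))
})

test_that("sim-vs-experiment comparison: identity, reversal, and constant input", {
  v <- setNames(c(1, 3, 2, 5, 4), sprintf("g%d", 1:5))
  expect_equal(compare_sim_vs_exp(v, v)$rho, 1)
  expect_equal(compare_sim_vs_exp(v, -v)$rho, -1)
  expect_error(compare_sim_vs_exp(v, v * 0), "constant")
})

test_that("simulated KO shifts correlate with fold changes derived from the same truth", {
  truth <- simulate_grn_truth(n_genes = 1000, n_tfs = 20, targets_per_tf = 40,
                              noise_sd = 0.5, seed = 85)
  ctrl <- simulate_grn_expression(truth, 300, seed = 86)
  ko_gene <- truth$tfs[1]
  b <- matrix(colMeans(ctrl), 1, dimnames = list(NULL, colnames(ctrl)))
  sim <- simulate_ko(truth$W, b, ko_gene, depth = 5, clipping = "none")
  # "experimental" KO from the same truth: cells drawn around the clamped
  # fixed point of the network with the regulator held at zero
  ko_truth <- truth
  ko_truth$baseline <- truth$baseline +
    oracle_ko_limit(truth$W, truth$baseline, ko_gene)
  exper <- simulate_grn_expression(ko_truth, 300, seed = 87)
  lfc <- setNames(log2(pmax(colMeans(exper), 0.01) / pmax(colMeans(ctrl), 0.01)),
                  colnames(ctrl))
  # shared gene universe: the network genes the knockout can reach
  affected <- names(which(abs(colMeans(sim$delta)) > 1e-12))
  cmp <- compare_sim_vs_exp(colMeans(sim$delta)[affected], lfc[affected])
  expect_gt(cmp$rho, 0.6)
})

test_that("kNN classification: exact hit, vote arithmetic, separated-cluster accuracy", {
  withr::with_seed(88, {
    atlas <- rbind(matrix(rnorm(300, 0, 1), 150, 2),
                   matrix(rnorm(300, 8, 1), 150, 2))
    labels <- rep(c("a", "b"), each = 150)
    # query equal to an atlas cell with k = 1
    one <- classify_knn(atlas[3, , drop = FALSE], atlas, labels, k = 1)
    expect_equal(one$cells$label, "a")
    expect_equal(unname(one$prob[1, "a"]), 1)
    # vote fractions: 30 of 50 neighbours labelled X
    grid <- rbind(matrix(0, 30, 2), matrix(1e-6, 20, 2))
    glabs <- rep(c("X", "Y"), c(30, 20))
    vote <- classify_knn(matrix(0, 1, 2), grid, glabs, k = 50)
    expect_equal(unname(vote$prob[1, ]), c(0.6, 0.4))
    expect_equal(vote$cells$label, "X")
    # probabilities always sum to 1
    q <- matrix(rnorm(60, 4, 3), 30, 2)
    res <- classify_knn(q, atlas, labels, k = 7)
    expect_equal(unname(rowSums(res$prob)), rep(1, 30))
    # held-out accuracy on separated clusters
    hq <- rbind(matrix(rnorm(100, 0, 1), 50, 2), matrix(rnorm(100, 8, 1), 50, 2))
    hres <- classify_knn(hq, atlas, labels, k = 15)
    expect_gt(mean(hres$cells$label == rep(c("a", "b"), each = 50)), 0.95)
    expect_error(classify_knn(q, atlas, labels, k = 1000), "atlas size")
  })
})

test_that("query embedding position is the mean of neighbour embedding positions", {
  atlas <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1), 4, 2, byrow = TRUE)
  emb <- atlas * 10
  res <- classify_knn(matrix(c(0.5, 0.5), 1), atlas, rep("a", 4),
                      atlas_embedding = emb, k = 4)
  expect_equal(res$cells$x, 5)
  expect_equal(res$cells$y, 5)
})

make_projection <- function(cells, k = 50) {
  labs <- sort(unique(cells$lab))
  prob <- matrix(0, nrow(cells), length(labs),
                 dimnames = list(cells$cell, labs))
  prob[cbind(seq_len(nrow(cells)), match(cells$lab, labs))] <- 1
  structure(list(cells = tibble::tibble(cell = cells$cell, label = cells$lab),
                 prob = prob, k = k),
            class = "projection_result")
}

test_that("abundance: equal composition centres on zero; halving gives log(0.5)", {
  withr::with_seed(92, {
    build <- function(n_het_x, n_ko_x, n_other = 400) {
      reps <- tibble::tibble(
        replicate = c("het1", "het2", "ko1", "ko2"),
        genotype = rep(c("het", "ko"), each = 2),
        n_x = c(n_het_x, n_het_x, n_ko_x, n_ko_x),
        n_o = n_other)
      cells <- purrr::pmap_dfr(reps, function(replicate, genotype, n_x, n_o) {
        tibble::tibble(cell = sprintf("%s_%04d", replicate, seq_len(n_x + n_o)),
                       replicate = replicate, genotype = genotype,
                       lab = rep(c("X", "other"), c(n_x, n_o)))
      })
      cells
    }
    eq <- build(100, 100)
    res_eq <- abundance_ci(make_projection(eq), eq[, c("cell", "replicate", "genotype")],
                           min_count = 10)
    x <- res_eq[res_eq$cluster == "X", ]
    expect_lt(abs(x$estimate), 0.2)
    expect_true(x$lower <= 0 && x$upper >= 0)

    # counts (100, 100) vs (50, 50) with equal offsets: effect = log(0.5)
    half <- build(100, 50, n_other = 400)
    res <- abundance_ci(make_projection(half),
                        half[, c("cell", "replicate", "genotype")],
                        min_count = 10)
    xh <- res[res$cluster == "X", ]
    # offsets differ slightly (450 vs 500 cells); closed form adjusts
    expected <- log(50 / 100) - log(450 / 500)
    expect_equal(xh$estimate, expected, tolerance = 1e-6)
  })
})

test_that("abundance flags diverging and low-count clusters", {
  cells <- tibble::tibble(cell = sprintf("c%03d", 1:40),
                          replicate = rep(c("h1", "k1"), each = 20),
                          genotype = rep(c("het", "ko"), each = 20),
                          lab = c(rep("X", 20), rep("Y", 20)))
  res <- abundance_ci(make_projection(cells), cells[, 1:3], min_count = 100)
  expect_true(all(is.na(res$estimate)))   # each cluster empty in one genotype
  expect_true(all(res$flagged))
})

test_that("quasi-Poisson reduces to the Poisson closed form at dispersion 1", {
  # with one replicate per genotype and equal offsets the GLM estimate is
  # exactly log(ratio); replicate as batch is omitted (single level)
  cells <- tibble::tibble(cell = sprintf("c%04d", 1:3000),
                          replicate = rep(c("h1", "k1"), each = 1500),
                          genotype = rep(c("het", "ko"), each = 1500),
                          lab = c(rep(c("X", "other"), c(300, 1200)),
                                  rep(c("X", "other"), c(150, 1350))))
  res <- abundance_ci(make_projection(cells), cells[, 1:3], min_count = 10)
  x <- res[res$cluster == "X", ]
  expect_equal(x$estimate, log(150 / 300), tolerance = 1e-8)
})

test_that("thymus filter applies the inclusive score bound and the sentinel", {
  cells <- tibble::tibble(cell = sprintf("c%d", 1:3), lab = "t1")
  prob <- rbind(c(0.5, 0.2, 0.2, 0.1),
                c(0.5, 0.19, 0.1, 0.21),
                c(0.6, 0.2, 0.1, 0.1))
  dimnames(prob) <- list(cells$cell, c("t1", "t2", "t3", "bg"))
  res <- structure(list(cells = tibble::tibble(cell = cells$cell, label = "t1"),
                        prob = prob, k = 50), class = "projection_result")
  counts <- matrix(c(1, 1, 0, 5, 5, 5), 3, 2,
                   dimnames = list(cells$cell, c("Il7", "other")))
  kept <- thymus_filter(res, counts, c("t1", "t2", "t3"), min_score = 0.8)
  # c1: score 0.9 & Il7 -> kept; c2: 0.79 -> out; c3: score 0.9, Il7 = 0 -> out
  expect_equal(kept, "c1")
  expect_error(thymus_filter(res, counts, "t1", sentinel_gene = "Foxn1"),
               "absent")
})

test_that("pseudotime bins are contiguous, near-equal, monotone", {
  b100 <- bin_pseudotime(sample(100), 20)
  expect_true(all(table(b100) == 5))
  b101 <- bin_pseudotime(seq_len(101), 20)
  tab <- table(b101)
  expect_equal(sort(unique(as.integer(tab))), c(5L, 6L))
  expect_equal(sum(tab == 6), 1)
  pt <- runif(57)
  bins <- bin_pseudotime(pt, 10)
  expect_true(all(diff(bins[order(pt)]) >= 0))
  expect_error(bin_pseudotime(1:5, 10), "More bins")
})

test_that("dynamic-gene screen: constants excluded, planted step genes included, null controlled", {
  withr::with_seed(95, {
    n <- 200
    counts <- matrix(rpois(n * 50, 20), n, 50,
                     dimnames = list(NULL, sprintf("g%02d", 1:50)))
    counts[, "g01"] <- 7                           # constant
    counts[, "g02"] <- rpois(n, rep(c(20, 45), each = n / 2))  # step, log2 fc > 1
    pt <- seq_len(n)
    dg <- dynamic_genes(counts, pt, n_periods = 10)
    expect_false(dg$selected[dg$gene == "g01"])
    expect_true(dg$selected[dg$gene == "g02"])
    # permuted pseudotime: selected fraction within binomial error of the
    # q cutoff
    dg_null <- dynamic_genes(counts[sample(n), ], pt, n_periods = 10)
    expect_lte(sum(dg_null$selected), 3)
  })
})

test_that("staging is self-consistent and rank-invariant to monotone transforms", {
  tr <- simulate_trajectory(n_cells = 400, n_genes = 150, n_dynamic = 30,
                            seed = 97)
  bins <- sprintf("b%02d", bin_pseudotime(tr$pseudotime, 20))
  bulks <- pseudobulk_profiles(tr$counts, bins)
  dyn <- tr$dynamic_genes
  # a bin staged against all bins tops at itself with r = 1
  sa <- stage_correlate(bulks[, "b07", drop = FALSE], bulks, dyn)
  top <- sa[sa$top2, ]
  expect_equal(top$bin[which.max(top$correlation)], "b07")
  expect_equal(max(sa$correlation), 1)
  expect_true(all(sa$correlation >= -1 & sa$correlation <= 1))
  # query built from cells of bins 9-10 stages into {8, 9, 10, 11}
  cells_9_10 <- bins %in% c("b09", "b10")
  q <- pseudobulk_profiles(tr$counts[cells_9_10, ], rep("q", sum(cells_9_10)))
  sq <- stage_correlate(q, bulks, dyn)
  expect_true(all(sq$bin[sq$top2] %in% c("b08", "b09", "b10", "b11")))
  # monotone per-profile transform of counts leaves rank correlations unchanged
  sq2 <- stage_correlate(q^3, bulks * 2 + 0, dyn)
  expect_equal(sq$correlation, sq2$correlation, tolerance = 1e-12)
})
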