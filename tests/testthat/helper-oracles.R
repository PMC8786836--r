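# Independent oracles used to check the package implementations on small
# instances. Each is written along a different computational route than the
# function it checks.

# Brute-force chromVAR-style raw deviations: explicit loops over motifs and
# cells, no linear algebra.
oracle_raw_deviation <- function(X, H) {
  X <- as.matrix(X); H <- as.matrix(H)
  grand <- sum(X)
  out <- matrix(NA_real_, ncol(H), nrow(X),
                dimnames = list(colnames(H), rownames(X)))
  for (m in seq_len(ncol(H))) {
    peaks_m <- which(H[, m] != 0)
    frac <- sum(colSums(X)[peaks_m]) / grand
    for (c in seq_len(nrow(X))) {
      expected <- sum(X[c, ]) * frac
      if (expected > 0) {
        out[m, c] <- (sum(X[c, peaks_m]) - expected) / expected
      }
    }
  }
  out
}

# All-pairs shortest-path betweenness by exhaustive simple-path enumeration
# (only viable for small digraphs).
oracle_betweenness <- function(edges, nodes) {
  adj <- lapply(setNames(nodes, nodes), function(v) {
    edges$target[edges$regulator == v]
  })
  paths_between <- function(s, t) {
    found <- list()
    walk <- function(path) {
      v <- path[length(path)]
      if (v == t) {
        found[[length(found) + 1L]] <<- path
        return(invisible())
      }
      for (w in adj[[v]]) if (!w %in% path) walk(c(path, w))
    }
    walk(s)
    found
  }
  bw <- setNames(numeric(length(nodes)), nodes)
  for (s in nodes) for (t in nodes) {
    if (s == t) next
    ps <- paths_between(s, t)
    if (!length(ps)) next
    lens <- lengths(ps)
    shortest <- ps[lens == min(lens)]
    for (v in setdiff(nodes, c(s, t))) {
      thru <- sum(vapply(shortest, function(p) v %in% p, logical(1)))
      bw[v] <- bw[v] + thru / length(shortest)
    }
  }
  bw
}

# Truncated-series knockout oracle via block matrices: after `depth` steps
# with the knockout clamped, the free genes carry
# sum_{j=0}^{depth-1} (W_FF')^j W_KF' delta_K.
oracle_ko_series <- function(W, baseline, ko, depth) {
  genes <- colnames(W)
  free <- setdiff(genes, ko)
  Wff <- t(W[free, free, drop = FALSE])
  Wkf <- t(W[ko, free, drop = FALSE])
  dK <- -baseline[ko]
  acc <- matrix(0, length(free), 1)
  term <- Wkf %*% dK
  for (j in seq_len(depth)) {
    acc <- acc + term
    term <- Wff %*% term
  }
  delta <- setNames(numeric(length(genes)), genes)
  delta[ko] <- -baseline[ko]
  delta[free] <- drop(acc)
  delta
}

# Analytic fixed point of the clamped propagation for a stable network.
oracle_ko_limit <- function(W, baseline, ko) {
  genes <- colnames(W)
  free <- setdiff(genes, ko)
  Wff <- t(W[free, free, drop = FALSE])
  Wkf <- t(W[ko, free, drop = FALSE])
  delta <- setNames(numeric(length(genes)), genes)
  delta[ko] <- -baseline[ko]
  delta[free] <- drop(solve(diag(length(free)) - Wff, Wkf %*% (-baseline[ko])))
  delta
}

# Ridge coefficients through the SVD route (implementation uses normal
# equations).
oracle_ridge_svd <- function(X, y, alpha) {
  s <- svd(X)
  drop(s$v %*% ((s$d / (s$d^2 + alpha)) * crossprod(s$u, y)))
}

# Least-squares fitted values by explicit normal equations (implementation
# uses QR).
oracle_normal_equations_resid <- function(X, design) {
  D <- cbind(1, design)
  beta <- solve(t(D) %*% D) %*% t(D) %*% X
  X - D %*% beta
}

# Small deterministic peak/gene builders shared by ATAC tests.
toy_peaks <- function(starts, chrom = "chr1", width = 501, score = NULL) {
  tibble::tibble(peak = sprintf("p%02d", seq_along(starts)), chrom = chrom,
                 start = starts, end = starts + width,
                 score = score %||% rep(0, length(starts)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
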