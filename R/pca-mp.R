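#' PCA with Marchenko-Pastur component retention
#'
#' Principal components of a cells x genes matrix, keeping the components
#' whose covariance eigenvalues exceed the Marchenko-Pastur upper edge
#' `sigma2 * (1 + sqrt(p / n))^2` — the largest eigenvalue expected from a
#' pure-noise covariance of unit-variance entries. For input standardized by
#' [regress_scale()], `sigma2 = 1` is the right reference.
#'
#' @param x Cells x genes matrix (dense or sparse). Centered per gene before
#'   decomposition; the centering means are stored for projection.
#' @param max_components Cap on the number of retained components.
#' @param sigma2 Noise variance of the MP reference (default 1).
#' @param use_mp If `FALSE`, retain exactly `max_components`.
#' @return An object of class `pca_mp`: gene `means`, orthonormal `loadings`
#'   (genes x components), covariance `eigenvalues`, `retained`, `mp_bound`,
#'   `n`, `p`, and the training `scores`.
#' @export
fit_pca_mp <- function(x, max_components = 100, sigma2 = 1, use_mp = TRUE) {
  X <- as_dense(x)
  n <- nrow(X); p <- ncol(X)
  if (n < 2 || p < 2) abort("Need at least 2 cells and 2 genes.")
  means <- colMeans(X)
  Xc <- sweep(X, 2, means)
  ## eigen-decomposition of the p x p sample covariance
  cov <- crossprod(Xc) / (n - 1)
  eig <- eigen(cov, symmetric = TRUE)
  eigenvalues <- pmax(eig$values, 0)
  mp_bound <- sigma2 * (1 + sqrt(p / n))^2
  retained <- if (use_mp) sum(eigenvalues > mp_bound) else max_components
  retained <- min(retained, max_components, p)
  k <- max(retained, 1L)  # keep at least one column so downstream shapes hold
  loadings <- eig$vectors[, seq_len(k), drop = FALSE]
  rownames(loadings) <- colnames(X)
  structure(list(means = setNames(means, colnames(X)), loadings = loadings,
                 eigenvalues = eigenvalues, retained = retained,
                 mp_bound = mp_bound, n = n, p = p,
                 scores = Xc %*% loadings),
            class = "pca_mp")
}

#' @export
print.pca_mp <- function(x, ...) {
  cat(sprintf("PCA (%d cells x %d genes): %d component(s) above MP bound %.4g\n",
              x$n, x$p, x$retained, x$mp_bound))
  invisible(x)
}

#' @describeIn fit_pca_mp One row per component: eigenvalue and retention.
#' @param x A `pca_mp` object.
#' @param ... Unused.
#' @export
tidy.pca_mp <- function(x, ...) {
  tibble(component = seq_along(x$eigenvalues),
         eigenvalue = x$eigenvalues,
         retained = seq_along(x$eigenvalues) <= x$retained)
}

#' @describeIn fit_pca_mp One-row model summary.
#' @export
glance.pca_mp <- function(x, ...) {
  tibble(n = x$n, p = x$p, mp_bound = x$mp_bound, retained = x$retained,
         total_variance = sum(x$eigenvalues))
}

#' Project query cells into a fitted atlas principal subspace
#'
#' Query expression is centered by the *atlas* gene means and multiplied by
#' the stored loading matrix, so atlas cells map exactly to their training
#' scores and external (e.g. knockout) cells land in the same coordinates.
#' Genes in the model but absent from the query are treated as zero after
#' centering (counted and warned about); a mismatch above
#' `max_missing_fraction` is an error.
#'
#' @param query Cells x genes matrix; column names are matched to the model's
#'   gene set.
#' @param model A [fit_pca_mp()] object.
#' @param components Number of leading components (default: retained).
#' @param max_missing_fraction Error if a larger fraction of model genes is
#'   missing from the query.
#' @return Dense query-cells x components coordinate matrix.
#' @export
project_cells <- function(query, model, components = NULL,
                          max_missing_fraction = 0.2) {
  stopifnot(inherits(model, "pca_mp"))
  k <- components %||% max(model$retained, 1L)
  k <- min(k, ncol(model$loadings))
  Q <- as_dense(query)
  genes <- names(model$means)
  if (is.null(colnames(Q))) {
    if (ncol(Q) != length(genes)) abort("Unnamed query must match the model's gene count.")
    colnames(Q) <- genes
  }
  missing <- setdiff(genes, colnames(Q))
  if (length(missing) / length(genes) > max_missing_fraction) {
    abort(sprintf("%d of %d model genes missing from query.",
                  length(missing), length(genes)))
  }
  if (length(missing)) {
    warn(sprintf("%d model gene(s) missing from query; treated as zero after centering.",
                 length(missing)))
  }
  Xc <- matrix(0, nrow(Q), length(genes),
               dimnames = list(rownames(Q), genes))
  present <- intersect(genes, colnames(Q))
  Xc[, present] <- sweep(Q[, present, drop = FALSE], 2, model$means[present])
  Xc %*% model$loadings[, seq_len(k), drop = FALSE]
}
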