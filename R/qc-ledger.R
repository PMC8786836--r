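#' Define a cell-level QC filter rule
#'
#' A rule names a per-cell metadata column and a threshold with a direction.
#' `"greater_than"`/`"less_than"` are strict (a cell sitting exactly on the
#' threshold is retained), matching the "over"/"under" wording of typical
#' filter descriptions; `"at_least"`/`"at_most"` are inclusive.
#'
#' @param name Human-readable rule name, used in the ledger.
#' @param field Metadata column the rule tests.
#' @param direction One of `"greater_than"`, `"less_than"`, `"at_least"`,
#'   `"at_most"`. Cells *matching* the predicate are removed.
#' @param threshold Finite numeric threshold.
#' @return An object of class `qc_rule`.
#' @export
#' @examples
#' qc_rule("high mito", "mito_fraction", "greater_than", 0.07)
qc_rule <- function(name, field,
                    direction = c("greater_than", "less_than", "at_least", "at_most"),
                    threshold) {
  direction <- match.arg(direction)
  if (!is.finite(threshold)) abort("`threshold` must be finite.")
  structure(list(name = name, field = field, direction = direction,
                 threshold = threshold),
            class = "qc_rule")
}

rule_violations <- function(rule, cells) {
  if (!rule$field %in% names(cells)) {
    abort(sprintf("Metadata field `%s` (rule \"%s\") is missing.",
                  rule$field, rule$name))
  }
  v <- cells[[rule$field]]
  switch(rule$direction,
         greater_than = v >  rule$threshold,
         less_than    = v <  rule$threshold,
         at_least     = v >= rule$threshold,
         at_most      = v <= rule$threshold)
}

new_ledger <- function(starting, entries, cells) {
  entries <- as_tibble(entries)
  per_sample <- NULL
  if ("sample" %in% names(cells)) {
    per_sample <- dplyr::count(cells, .data$sample, name = "cells")
  }
  structure(entries,
            starting_count = starting,
            final_count = if (nrow(entries)) entries$remaining[nrow(entries)] else starting,
            per_sample = per_sample,
            class = c("qc_ledger", class(entries)))
}

#' Apply cell-level filter rules in order, producing an auditable ledger
#'
#' Rules are applied sequentially; a cell failing several rules is removed
#' once and attributed to the *first* rule it fails, so the ledger telescopes:
#' each entry's `remaining` equals the previous `remaining` minus its
#' `removed`, and the final count equals the starting count minus the sum of
#' all removals.
#'
#' @param cells Per-cell metadata tibble (one row per cell).
#' @param rules List of [qc_rule()]s, applied in order.
#' @param counts Optional cells x genes count matrix, subset alongside.
#' @return A list with `cells` (retained metadata), `counts` (or `NULL`), and
#'   `ledger` (a `qc_ledger` tibble with columns `rule`, `removed`,
#'   `remaining`; attributes `starting_count`, `final_count`, `per_sample`).
#' @export
apply_cell_filters <- function(cells, rules, counts = NULL) {
  cells <- as_tibble(cells)
  if (inherits(rules, "qc_rule")) rules <- list(rules)
  keep <- rep(TRUE, nrow(cells))
  entries <- vector("list", length(rules))
  for (i in seq_along(rules)) {
    bad <- rule_violations(rules[[i]], cells) & keep
    bad[is.na(bad)] <- FALSE
    keep <- keep & !bad
    entries[[i]] <- tibble(rule = rules[[i]]$name,
                           removed = sum(bad), remaining = sum(keep))
  }
  kept <- cells[keep, , drop = FALSE]
  list(cells = kept,
       counts = if (!is.null(counts)) as_counts(counts)[keep, , drop = FALSE],
       ledger = new_ledger(nrow(cells), bind_rows(entries), kept))
}

#' Remove whole clusters of cells, with per-cluster ledger entries
#'
#' @param cells Per-cell metadata tibble.
#' @param cluster_col Name of the column holding cluster labels.
#' @param excluded Cluster labels to remove (all their cells, and only them).
#' @param counts Optional cells x genes count matrix, subset alongside.
#' @return As [apply_cell_filters()]: `cells`, `counts`, `ledger` with one
#'   entry per excluded cluster.
#' @export
apply_cluster_exclusions <- function(cells, cluster_col, excluded, counts = NULL) {
  cells <- as_tibble(cells)
  require_columns(cells, cluster_col, "cells")
  labels <- as.character(cells[[cluster_col]])
  unknown <- setdiff(as.character(excluded), unique(labels))
  if (length(unknown)) {
    abort(sprintf("Unknown cluster id(s): %s", paste(unknown, collapse = ", ")))
  }
  keep <- rep(TRUE, nrow(cells))
  entries <- vector("list", length(excluded))
  for (i in seq_along(excluded)) {
    bad <- labels == as.character(excluded[[i]]) & keep
    keep <- keep & !bad
    entries[[i]] <- tibble(rule = sprintf("cluster %s", excluded[[i]]),
                           removed = sum(bad), remaining = sum(keep))
  }
  kept <- cells[keep, , drop = FALSE]
  list(cells = kept,
       counts = if (!is.null(counts)) as_counts(counts)[keep, , drop = FALSE],
       ledger = new_ledger(nrow(cells), bind_rows(entries), kept))
}

#' Doublet removal quota
#'
#' The number of highest-doublet-enrichment cells to remove from a sample of
#' `n_cells`: `floor(n_cells^2 / divisor)`. The divisor defaults to 100,000,
#' the value consistent with published per-sample removal counts (e.g. 186 of
#' 4320 cells).
#'
#' @param n_cells Cells in the sample (>= 0).
#' @param divisor Positive quota divisor.
#' @return Integer quota.
#' @export
doublet_quota <- function(n_cells, divisor = 1e5) {
  stopifnot(n_cells >= 0, divisor > 0)
  as.integer(floor(n_cells^2 / divisor))
}

#' Remove each sample's doublet quota of highest-enrichment cells
#'
#' Per sample, the [doublet_quota()] of that sample's size is removed, taking
#' the cells with the highest doublet enrichment (ties broken by input
#' order). One ledger entry is produced per sample.
#'
#' @param cells Per-cell metadata tibble with a sample column and a doublet
#'   enrichment score column.
#' @param score_col Doublet enrichment column name.
#' @param sample_col Sample column name (default `"sample"`).
#' @param divisor Quota divisor passed to [doublet_quota()].
#' @param counts Optional cells x genes count matrix, subset alongside.
#' @return As [apply_cell_filters()]: `cells`, `counts`, `ledger`.
#' @export
apply_doublet_quota <- function(cells, score_col = "doublet_enrichment",
                                sample_col = "sample", divisor = 1e5,
                                counts = NULL) {
  cells <- as_tibble(cells)
  require_columns(cells, c(score_col, sample_col), "cells")
  samples <- unique(cells[[sample_col]])
  keep <- rep(TRUE, nrow(cells))
  entries <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    rows <- which(cells[[sample_col]] == samples[[i]])
    quota <- doublet_quota(length(rows), divisor)
    if (quota > 0) {
      worst <- rows[order(-cells[[score_col]][rows])[seq_len(quota)]]
      keep[worst] <- FALSE
    }
    entries[[i]] <- tibble(rule = sprintf("doublet quota %s", samples[[i]]),
                           removed = quota, remaining = sum(keep))
  }
  kept <- cells[keep, , drop = FALSE]
  list(cells = kept,
       counts = if (!is.null(counts)) as_counts(counts)[keep, , drop = FALSE],
       ledger = new_ledger(nrow(cells), bind_rows(entries), kept))
}

#' Add log-normalized expression of selected genes to cell metadata
#'
#' Per-cell scaling to `scale_to` total counts, then `log(x + 1)` in the given
#' base; used e.g. to express a haemoglobin-contamination rule as a metadata
#' threshold.
#'
#' @param cells Per-cell metadata tibble.
#' @param counts Cells x genes count matrix.
#' @param genes Gene names to add; columns are named `lognorm_<gene>`.
#' @param scale_to Per-cell total after scaling.
#' @param base Logarithm base (2 for atlas-style, `exp(1)` for KO-style).
#' @return `cells` with one extra column per gene.
#' @export
add_log_normalized <- function(cells, counts, genes, scale_to = 1e4, base = 2) {
  counts <- as_counts(counts)
  missing <- setdiff(genes, colnames(counts))
  if (length(missing)) {
    abort(sprintf("Gene(s) absent from counts: %s", paste(missing, collapse = ", ")))
  }
  ln <- log_normalize(counts, scale_to, base)
  for (gene in genes) {
    cells[[paste0("lognorm_", gene)]] <- as.numeric(ln[, gene])
  }
  cells
}

#' Combine sequential ledgers into one audit trail
#'
#' @param ... `qc_ledger` objects from successive filtering stages, in order.
#' @return A single `qc_ledger` whose starting count is the first stage's and
#'   whose entries are concatenated.
#' @export
combine_ledgers <- function(...) {
  ledgers <- list(...)
  stopifnot(length(ledgers) >= 1, all(vapply(ledgers, inherits, TRUE, "qc_ledger")))
  entries <- bind_rows(lapply(ledgers, as_tibble))
  structure(entries,
            starting_count = attr(ledgers[[1]], "starting_count"),
            final_count = attr(ledgers[[length(ledgers)]], "final_count"),
            per_sample = attr(ledgers[[length(ledgers)]], "per_sample"),
            class = c("qc_ledger", class(entries)))
}

#' @export
print.qc_ledger <- function(x, ...) {
  cat(sprintf("QC ledger: %d -> %d cells\n",
              attr(x, "starting_count"), attr(x, "final_count")))
  print(as_tibble(x), ...)
  invisible(x)
}

#' Write a ledger as TSV and JSON
#'
#' @param ledger A `qc_ledger`.
#' @param path_tsv,path_json Output paths (either may be `NULL` to skip).
#' @return The ledger, invisibly.
#' @export
write_ledger <- function(ledger, path_tsv = NULL, path_json = NULL) {
  stopifnot(inherits(ledger, "qc_ledger"))
  if (!is.null(path_tsv)) readr::write_tsv(as_tibble(ledger), path_tsv)
  if (!is.null(path_json)) {
    jsonlite::write_json(
      list(starting_count = attr(ledger, "starting_count"),
           entries = as_tibble(ledger),
           final_count = attr(ledger, "final_count"),
           per_sample = attr(ledger, "per_sample")),
      path_json, auto_unbox = TRUE, digits = NA)
  }
  invisible(ledger)
}
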