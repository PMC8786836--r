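# Readers/writers for the plain-text interchange formats the pipeline uses:
# MatrixMarket count directories, BED peak files, and TSV tables.

#' Write a count matrix as MTX + barcodes + features, with cell metadata
#'
#' @param counts Cells x genes count matrix.
#' @param dir Output directory (created if needed).
#' @param cells Optional per-cell metadata tibble, written as
#'   `cells.tsv`.
#' @return `dir`, invisibly.
#' @export
write_mtx_dir <- function(counts, dir, cells = NULL) {
  counts <- as_counts(counts)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ## conventional orientation: features x cells
  Matrix::writeMM(Matrix::t(counts), file.path(dir, "matrix.mtx"))
  readr::write_tsv(tibble(barcode = rownames(counts)),
                   file.path(dir, "barcodes.tsv"), col_names = FALSE)
  readr::write_tsv(tibble(feature = colnames(counts)),
                   file.path(dir, "features.tsv"), col_names = FALSE)
  if (!is.null(cells)) readr::write_tsv(cells, file.path(dir, "cells.tsv"))
  invisible(dir)
}

#' Read a count directory written by [write_mtx_dir()]
#'
#' @param dir Directory with `matrix.mtx`, `barcodes.tsv`, `features.tsv`
#'   and optionally `cells.tsv`.
#' @return List with `counts` (cells x genes sparse matrix) and `cells`
#'   (tibble or `NULL`).
#' @export
read_mtx_dir <- function(dir) {
  m <- Matrix::t(methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                             "CsparseMatrix"))
  barcodes <- readr::read_tsv(file.path(dir, "barcodes.tsv"),
                              col_names = "barcode", show_col_types = FALSE)
  features <- readr::read_tsv(file.path(dir, "features.tsv"),
                              col_names = "feature", show_col_types = FALSE)
  dimnames(m) <- list(barcodes$barcode, features$feature)
  cells_path <- file.path(dir, "cells.tsv")
  cells <- if (file.exists(cells_path)) {
    readr::read_tsv(cells_path, show_col_types = FALSE)
  }
  list(counts = m, cells = cells)
}

#' Write peaks as a BED file (0-based half-open)
#'
#' @param peaks Tibble with `chrom`, `start`, `end` and optionally `peak`
#'   (name) and `score`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  require_columns(peaks, c("chrom", "start", "end"), "peaks")
  out <- tibble(chrom = peaks$chrom, start = peaks$start, end = peaks$end,
                name = peaks$peak %||% sprintf("peak%d", seq_len(nrow(peaks))),
                score = peaks$score %||% 0)
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read a BED file into a peak tibble
#'
#' @param path BED file path (at least 3 columns; name/score used if present).
#' @return Tibble with `chrom`, `start`, `end` (+ `peak`, `score`).
#' @export
read_bed <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  out <- tibble(chrom = as.character(raw[[1]]),
                start = as.numeric(raw[[2]]), end = as.numeric(raw[[3]]))
  if (ncol(raw) >= 4) out$peak <- as.character(raw[[4]])
  if (ncol(raw) >= 5) out$score <- as.numeric(raw[[5]])
  out
}
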