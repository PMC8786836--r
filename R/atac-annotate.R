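# Peak geometry: annotation against gene models, and iterative-overlap
# merging of fixed-width peak sets. Coordinates are BED-style 0-based
# half-open throughout; conversion to the 1-based closed convention of
# IRanges happens at the boundary.

to_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1, end = df$end))
}

# Strand-aware promoter windows as 0-based half-open intervals:
# 2000 bp upstream of the TSS and 100 bp downstream (inclusive on the genome,
# then converted), flipped for minus-strand genes.
promoter_windows <- function(tss, upstream = 2000, downstream = 100) {
  require_columns(tss, c("chrom", "tss", "strand"), "tss")
  plus <- tss$strand != "-"
  tibble(gene = tss$gene %||% seq_len(nrow(tss)),
         chrom = tss$chrom,
         start = pmax(0, ifelse(plus, tss$tss - upstream, tss$tss - downstream)),
         end = ifelse(plus, tss$tss + downstream + 1, tss$tss + upstream + 1))
}

#' Annotate peaks as promoter, exonic, intronic or distal
#'
#' Promoter means any overlap with the strand-aware window 2000 bp upstream
#' to 100 bp downstream of a TSS; exonic means overlap with any exon;
#' intronic means overlap with a gene body but no exon; everything else is
#' distal. Precedence is promoter > exonic > intronic > distal, independent
#' of peak order.
#'
#' @param peaks Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param tss Gene table with `gene`, `chrom`, `tss` (0-based position),
#'   `strand`; optionally `start`/`end` for the gene body.
#' @param exons Optional exon table (`chrom`, `start`, `end`).
#' @param upstream,downstream Promoter window extents in bp.
#' @return `peaks` with an `annotation` factor column.
#' @export
annotate_peaks <- function(peaks, tss, exons = NULL,
                           upstream = 2000, downstream = 100) {
  peaks <- as_tibble(peaks)
  require_columns(peaks, c("chrom", "start", "end"), "peaks")
  unknown <- setdiff(unique(peaks$chrom), unique(tss$chrom))
  if (length(unknown)) {
    abort(sprintf("Peak chromosome(s) absent from the gene table: %s",
                  paste(unknown, collapse = ", ")))
  }
  pk <- to_granges(peaks)
  prom <- to_granges(promoter_windows(tss, upstream, downstream))
  is_prom <- IRanges::overlapsAny(pk, prom)
  is_exon <- if (!is.null(exons) && nrow(exons)) {
    IRanges::overlapsAny(pk, to_granges(exons))
  } else rep(FALSE, nrow(peaks))
  is_body <- if (all(c("start", "end") %in% names(tss))) {
    IRanges::overlapsAny(pk, to_granges(tss))
  } else rep(FALSE, nrow(peaks))
  ann <- ifelse(is_prom, "promoter",
                ifelse(is_exon, "exonic",
                       ifelse(is_body, "intronic", "distal")))
  peaks$annotation <- factor(ann, levels = c("promoter", "exonic", "intronic", "distal"))
  peaks
}

#' Merge overlapping peak sets by iterative overlap removal
#'
#' Greedy, by descending significance score: the best remaining peak is
#' retained and every peak overlapping it is discarded; this repeats until no
#' peaks remain. Optionally, retained peaks are then required to be supported
#' by (overlap with) at least `min_support` of the original replicate peak
#' sets.
#'
#' @param peaks Tibble with `chrom`, `start`, `end`, `score`, and optionally
#'   `replicate` (identifier of the source pseudobulk replicate).
#' @param min_support If > 1 and `replicate` is present, retained peaks must
#'   overlap peaks from at least this many distinct replicates.
#' @return Tibble of retained, pairwise non-overlapping peaks.
#' @export
merge_iterative_overlap <- function(peaks, min_support = 1) {
  peaks <- as_tibble(peaks)
  require_columns(peaks, c("chrom", "start", "end", "score"), "peaks")
  if (!nrow(peaks)) return(peaks)
  ord <- order(-peaks$score)
  gr <- to_granges(peaks)
  hits <- GenomicRanges::findOverlaps(gr, gr)
  nbr <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
  alive <- rep(TRUE, nrow(peaks))
  kept <- logical(nrow(peaks))
  for (i in ord) {
    if (!alive[i]) next
    kept[i] <- TRUE
    alive[nbr[[as.character(i)]]] <- FALSE
  }
  out <- peaks[kept, , drop = FALSE]
  if (min_support > 1 && "replicate" %in% names(peaks)) {
    og <- to_granges(out)
    support <- vapply(seq_len(nrow(out)), function(i) {
      h <- GenomicRanges::findOverlaps(og[i], gr)
      length(unique(peaks$replicate[S4Vectors::subjectHits(h)]))
    }, numeric(1))
    out <- out[support >= min_support, , drop = FALSE]
  }
  out
}
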