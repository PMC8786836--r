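#' Specification for a synthetic scATAC-seq experiment
#'
#' Fixed-width (501 bp) peaks are placed on a toy genome with a configurable
#' fraction overlapping strand-aware promoter windows of a TSS table, a
#' fraction of peaks made cluster-specific, and a binary peak-by-motif hit
#' matrix. Insertion counts are capped Poisson, mirroring the convention of
#' counting at most 4 insertions per peak per cell.
#'
#' @param n_cells,n_peaks,n_clusters Dataset dimensions.
#' @param genome Tibble with columns `chrom`, `length` (bp).
#' @param tss Optional tibble of genes (`gene`, `chrom`, `tss`, `strand`);
#'   generated at random when `NULL`.
#' @param n_genes Number of generated TSS entries when `tss` is `NULL`.
#' @param fraction_promoter_peaks Fraction of peaks planted to overlap a
#'   promoter window (2000 bp upstream / 100 bp downstream of a TSS).
#' @param cluster_specific_fraction Fraction of peaks boosted in exactly one
#'   cluster (these carry a `specific_cluster` label in the peak table).
#' @param specific_boost Fold-boost of a specific peak in its home cluster.
#' @param n_motifs,motif_hit_density Binary motif-hit matrix dimensions and
#'   Bernoulli hit density.
#' @param max_insertions Cap on per-peak per-cell insertion counts (default 4).
#' @param peak_width Fixed peak width in bp (default 501).
#' @param mean_insertions Poisson mean of per-peak per-cell insertions for an
#'   average accessible peak, before capping.
#' @param seed Integer seed.
#' @return An object of class `scatac_sim_spec`.
#' @export
scatac_sim_spec <- function(n_cells = 300,
                            n_peaks = 800,
                            n_clusters = 4,
                            genome = tibble(chrom = c("chr1", "chr2"),
                                            length = c(5e7, 5e7)),
                            tss = NULL,
                            n_genes = 60,
                            fraction_promoter_peaks = 0.3,
                            cluster_specific_fraction = 0.2,
                            specific_boost = 6,
                            n_motifs = 15,
                            motif_hit_density = 0.05,
                            max_insertions = 4L,
                            peak_width = 501L,
                            mean_insertions = 0.3,
                            seed = 1L) {
  stopifnot(fraction_promoter_peaks >= 0, fraction_promoter_peaks <= 1,
            cluster_specific_fraction >= 0, cluster_specific_fraction <= 1)
  structure(
    list(n_cells = as.integer(n_cells), n_peaks = as.integer(n_peaks),
         n_clusters = as.integer(n_clusters), genome = genome, tss = tss,
         n_genes = as.integer(n_genes),
         fraction_promoter_peaks = fraction_promoter_peaks,
         cluster_specific_fraction = cluster_specific_fraction,
         specific_boost = specific_boost,
         n_motifs = as.integer(n_motifs),
         motif_hit_density = motif_hit_density,
         max_insertions = as.integer(max_insertions),
         peak_width = as.integer(peak_width),
         mean_insertions = mean_insertions,
         seed = as.integer(seed)),
    class = "scatac_sim_spec")
}

#' Simulate a clustered scATAC-seq peak-by-cell insertion matrix
#'
#' @param spec An [scatac_sim_spec()].
#' @return A list of class `scatac_sim`: `counts` (sparse cells x peaks,
#'   entries in 0..`max_insertions`), `peaks` (tibble with 0-based half-open
#'   `chrom`/`start`/`end`, `gc`, and `specific_cluster`), `motif_hits`
#'   (sparse binary peaks x motifs), `tss`, and `cells`.
#' @export
simulate_scatac <- function(spec) {
  stopifnot(inherits(spec, "scatac_sim_spec"))
  with_seed_local(spec$seed, {
    w <- spec$peak_width
    genome <- spec$genome
    if (sum(floor(genome$length / (2 * w))) < spec$n_peaks) {
      abort("Genome too small for the requested number of peaks.")
    }

    tss <- spec$tss
    if (is.null(tss)) {
      chrom <- sample(genome$chrom, spec$n_genes, replace = TRUE)
      len <- genome$length[match(chrom, genome$chrom)]
      tss <- tibble(gene = sprintf("g%03d", seq_len(spec$n_genes)),
                    chrom = chrom,
                    tss = floor(runif(spec$n_genes, 1e4, len - 1e4)),
                    strand = sample(c("+", "-"), spec$n_genes, replace = TRUE))
    }
    prom_windows <- promoter_windows(tss)

    n_prom <- round(spec$fraction_promoter_peaks * spec$n_peaks)
    n_dist <- spec$n_peaks - n_prom

    ## promoter peaks: centered on a sampled TSS, guaranteed window overlap
    prom <- NULL
    if (n_prom > 0) {
      pick <- sample.int(nrow(tss), n_prom, replace = TRUE)
      prom <- tibble(chrom = tss$chrom[pick],
                     start = pmax(0, tss$tss[pick] - (w - 1L) %/% 2L))
      prom$end <- prom$start + w
    }

    ## distal peaks: rejection-sampled away from promoter windows and from
    ## already-placed peaks
    placed <- if (is.null(prom)) tibble(chrom = character(), start = numeric(),
                                        end = numeric()) else prom
    distal <- list()
    tries <- 0L
    while (length(distal) < n_dist) {
      tries <- tries + 1L
      if (tries > 200L * spec$n_peaks) abort("Could not place non-overlapping peaks; genome too small.")
      ch <- sample(genome$chrom, 1)
      len <- genome$length[genome$chrom == ch]
      s <- floor(runif(1, 0, len - w))
      cand <- c(s, s + w)
      pw <- prom_windows[prom_windows$chrom == ch, ]
      if (any(cand[1] < pw$end & cand[2] > pw$start)) next
      pl <- placed[placed$chrom == ch, ]
      if (any(cand[1] < pl$end & cand[2] > pl$start)) next
      distal[[length(distal) + 1L]] <- tibble(chrom = ch, start = s, end = s + w)
      placed <- bind_rows(placed, distal[[length(distal)]])
    }
    peaks <- bind_rows(prom, bind_rows(distal))
    peaks <- peaks[order(peaks$chrom, peaks$start), ]
    peaks$peak <- sprintf("peak%05d", seq_len(nrow(peaks)))
    peaks$gc <- runif(nrow(peaks), 0.3, 0.7)

    ## cluster-specific peaks
    n_spec <- round(spec$cluster_specific_fraction * spec$n_peaks)
    peaks$specific_cluster <- NA_integer_
    if (n_spec > 0) {
      sp <- sample.int(nrow(peaks), n_spec)
      peaks$specific_cluster[sp] <- sample.int(spec$n_clusters, n_spec, replace = TRUE)
    }

    cluster <- sample.int(spec$n_clusters, spec$n_cells, replace = TRUE)
    base_rate <- rlnorm(nrow(peaks), log(spec$mean_insertions), 0.4)
    depth_factor <- rlnorm(spec$n_cells, 0, 0.25)

    lambda <- outer(depth_factor, base_rate)
    for (k in seq_len(spec$n_clusters)) {
      cols <- which(peaks$specific_cluster == k)
      rows <- which(cluster == k)
      if (!length(cols) || !length(rows)) next
      lambda[rows, cols] <- lambda[rows, cols] * spec$specific_boost
      lambda[-rows, cols] <- lambda[-rows, cols] / spec$specific_boost
    }
    counts <- matrix(rpois(length(lambda), lambda), nrow(lambda), ncol(lambda))
    counts <- pmin(counts, spec$max_insertions)
    dimnames(counts) <- list(sprintf("cell%05d", seq_len(spec$n_cells)), peaks$peak)

    motif_hits <- Matrix::sparseMatrix(
      i = integer(0), j = integer(0), x = numeric(0),
      dims = c(nrow(peaks), spec$n_motifs),
      dimnames = list(peaks$peak, sprintf("motif%02d", seq_len(spec$n_motifs))))
    hits <- which(matrix(runif(nrow(peaks) * spec$n_motifs) < spec$motif_hit_density,
                         nrow(peaks), spec$n_motifs), arr.ind = TRUE)
    if (nrow(hits)) {
      motif_hits <- Matrix::sparseMatrix(i = hits[, 1], j = hits[, 2], x = 1,
                                         dims = dim(motif_hits),
                                         dimnames = dimnames(motif_hits))
    }

    structure(list(counts = methods::as(counts, "CsparseMatrix"),
                   peaks = as_tibble(peaks[, c("peak", "chrom", "start", "end",
                                               "gc", "specific_cluster")]),
                   motif_hits = motif_hits, tss = tss,
                   cells = tibble(cell = rownames(counts), true_cluster = cluster),
                   spec = spec),
              class = "scatac_sim")
  })
}
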