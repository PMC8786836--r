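---
title: "Models and methods behind the pharynet pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the pharynet pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharynet)
```

`pharynet` packages the bespoke computational steps of a multi-omic
(scRNA + scATAC) developmental-atlas analysis of pharyngeal endoderm — the
embryonic tissue that produces thymus, parathyroid and ultimobranchial
body — as reusable, tested functions. This vignette explains the models and
procedures, the parameters that matter, the synthetic data the tests run
on, and the numerical and design choices made where the procedure itself
leaves room.

## QC ledgers

Cell exclusion happens in an explicit order: whole contaminant clusters
first, then per-cell threshold rules. A cell failing several rules is
counted once, against the *first* rule it fails, so the resulting ledger
telescopes and its arithmetic is auditable: each entry's `remaining` is the
previous `remaining` minus its `removed`, and the final count is the start
minus the column sum.

Directional wording is taken literally: "over 7% mitochondrial UMIs" is a
strict `>` (a cell at exactly 7% stays), "under 1%" a strict `<`, "at
least" is inclusive. The haemoglobin rule operates on log-normalized
expression — counts scaled to 10,000 per cell, then `log(x + 1)` — with the
log base a parameter because the atlas-style preprocessing uses base 2 and
the knockout-style preprocessing the natural log.

The per-sample doublet quota is `floor(n² / divisor)`. The divisor defaults
to 100,000: that is the value consistent with the reported per-sample
removals (e.g. 186 of 4320 cells, since `floor(4320²/10⁵) = 186`), although
the formula is sometimes quoted with 10,000. Both are available via the
`divisor` argument; the discrepancy is recorded rather than resolved.

The replay presets (`atlas_qc_spec()`, `ko_qc_spec()`,
`atac_doublet_cells()`, `atac_cluster_cells()`) treat the published
exclusion structure — cluster sizes 459/79/381/247/231, rule removals
2122/270/17, the knockout-side 3362/1150/318/207/132/37 + 2121 + 45, and
the scATAC per-sample sizes — as input data and plant exactly that
structure into synthetic metadata. Running the ledger machinery over them
reproduces 54,044, 21,904, 13,396 and 10,890 cells exactly; this checks the
accounting logic, not the biology.

## Batch-aware dimensionality reduction

The batch-correction design has `d = 1 + 3 + Σ_t (r_t − 1)` columns: the
per-cell total UMI count, three cell-cycle phase indicators (G1/S/G2M), and
for every timepoint with `r` replicates, `r − 1` sequential contrasts
(+1 for replicate `j`, −1 for replicate `j+1`, 0 elsewhere; further
contrasts are linear combinations of these and are omitted). The 2/3/3/2
replicate structure gives `d = 10`. All three phase indicators are kept even
though they sum to the intercept; the projection is computed through a
pivoted QR, so the redundant direction is dropped numerically rather than
by hand, and a warning is reserved for deficiency beyond that expected one.

Variable genes are selected on *normalized, non-log* counts: per gene, the
dispersion is `log(residual variance / mean)`, where the residual variance
comes from least-squares regression on the design — so variance explained
by depth, phase or replicate cannot masquerade as biological variability.
Dispersions are z-scored within 20 equal-count mean bins (the legacy
variable-gene convention) and genes pass at `mean > 0.1`, scaled dispersion
`> 0.8` by default. A gene fit exactly by the covariates has residual
variance 0 and dispersion −∞; numerically, residual variance below
`10⁻¹² ×` the gene's total variance is treated as exactly zero.

Scaling regresses each (log-normalized) gene on the design, subtracts the
fitted values and divides by the residual standard deviation; exact fits
map to all-zero columns rather than amplified noise.

Principal components are retained above the Marchenko–Pastur upper edge
`σ²(1 + √(p/n))²` with `σ² = 1` for unit-scaled input (`p` genes, `n`
cells). This is the asymptotic upper edge of the pure-noise eigenvalue
distribution. A caveat worth stating precisely: for finite matrices the
largest noise eigenvalue fluctuates around that edge (Tracy–Widom), landing
*above* it in roughly 8% of standardized-Gaussian datasets at
`n = 2000, p = 200`. So "pure noise retains zero components" holds in about
92% of seeds at that size, not in ~100%; the bound is the standard,
spec-level choice, and the fluctuation is a property of the statistic, not
a bug in the implementation.

Projection centers query cells by the *atlas* gene means and applies the
atlas loadings, so training cells reproduce their scores exactly and
knockout cells land in the same coordinates. Both scaled-PCA (atlas-style)
and unscaled-PCA-on-selected-genes (knockout-style) uses are supported,
because the two preprocessing conventions differ; missing query genes are
zero after centering, counted, and allowed up to a configurable fraction.

## Chromatin features

Coordinates are BED-style 0-based half-open throughout; conversion to the
1-based closed convention happens only at the IRanges boundary. The
promoter window spans 2000 bp upstream to 100 bp downstream of the TSS,
flipped on minus-strand genes; annotation precedence is promoter > exonic >
intronic > distal, independent of peak order. Iterative-overlap merging is
greedy by descending significance: keep the best peak, discard everything
overlapping it, repeat; an optional filter then requires support from at
least two replicate peak sets.

The cluster-specificity index of a peak is `τ = Σᵢ (1 − xᵢ)/(N − 1)`, where
`xᵢ` is the cluster-mean signal (log2 of depth-scaled means + 1),
max-normalized so the top cluster is 1: τ is 0 for a uniformly accessible
peak and 1 for a single-cluster peak. All-zero peaks are reported as `NA`
rather than 0.

Motif deviation scores follow the chromVAR recipe: per motif and cell, the
raw deviation is `(observed − expected)/expected`, with the expectation
from cell-independent peak usage; bias correction z-scores the raw value
against 50 background peak sets matched on GC and mean accessibility. The
background matching uses 10 × 10 decile bins sampled with replacement —
the published procedure fixes 50 backgrounds but not the binning, so the
binning is a package choice. Expectations are computed on raw insertion
counts with cell totals (not depth-normalized); this too is exposed.

Motif–gene pairing: the per-cluster motif score is the cluster-mean
deviation minus the minimum cluster mean (the flattest cluster scores 0);
each motif takes its best-correlated same-family gene, is assigned to the
cluster where its score peaks, and when two motifs claim one gene the
higher-scoring motif wins. Pairs are retained at correlation > 0.35 with a
motif score in the cluster's top decile, boundary ties included.

## GRN construction

Co-accessibility is computed over low-overlapping aggregates of cells:
random seed cells plus their `k − 1 = 99` nearest neighbours in the reduced
space, accepted only if the overlap with every accepted aggregate is at
most 0.8; with 500 draws this yields a few hundred aggregates. Aggregate
counts are depth-scaled and log2-transformed; Pearson correlations are
taken for same-chromosome peak pairs whose midpoints lie within 250 kb
(midpoints because the anchor is otherwise unspecified and the midpoint is
symmetric). P-values come from the correlation t-statistic with
`(aggregates − 2)` degrees of freedom, BH-adjusted; pairs are retained at
FDR < 10⁻¹⁰, r ≥ 0.5, and both peaks above the 0.35 variance *quantile*
across the peak set — the published variability cutoff's unit is ambiguous,
so the quantile reading is the default and the parameter is exposed.

The base GRN links a peak to a gene if it overlaps the TSS (strength 1) or
is co-accessible (≥ 0.5) with a TSS peak of that gene; candidate regulators
are the TFs whose motifs hit a linked peak. Per cluster and target, a ridge
regression (α = 10, no intercept, columns centered within the cluster) on
the candidate regulators is bagged over 20 bootstrap resamples of size `n`
(the bag size and replacement policy are unstated in the source procedure;
the bootstrap default is recorded as an assumption). The edge weight is the
mean bagged coefficient; the edge p-value a two-sided one-sample t-test of
the bagged coefficients against zero — the same statistic the reference
implementation uses. Edges survive at `p ≤ 0.001`, `|w| > 0.005`, regulator
in the cluster's marker set; survivors are refit.

One calibration fact matters for interpreting the pruning: because the
bagged mean is essentially the full-sample estimate while the bag spread
estimates its sampling error, the bag-level t statistic is about
`√20 ≈ 4.5` times the usual z statistic, and a truly null edge passes
`p ≤ 0.001` with probability ≈ 0.38 (it still must clear the weight and
marker filters). The p filter therefore removes the worst half of noise
edges rather than all of them; precision in practice comes from the base
GRN restricting candidates. The edge-recovery test mirrors this: candidate
sets contain the true regulators plus a 25% decoy fraction, emulating a
motif-informed prior with a moderate false-hit rate, which puts expected
precision near 0.9 at 2000 cells.

Network statistics use directed, unweighted betweenness (unnormalized
shortest-path counts) and outdegree; expression specificity is the
cluster-mean divided by the median cluster-mean. Regulator ranking drops
edges below |weight| 0.01, sorts by the size of the intersection of target
sets with a focus gene list (ties lexicographic, so ranks are
deterministic), and partitions the top-200 subgraph with Leiden at
resolution 2 (the partitioner is pluggable); subnetwork activity is the
mean expression of a community's genes per cluster.

## Knockout simulation, projection, abundance, staging

The in-silico knockout clamps the knocked-out genes at a shift of
−baseline (expression 0) and iterates `δ ← W'δ` for `depth = 5` steps,
re-applying the clamp each step. The final state equals the truncated
series `Σ_{j<depth} (W_FF')ʲ W_KF' δ_K` on the free genes — whether the
published depth-5 propagation accumulates shifts or takes the final state
is unstated; the clamped-iteration semantics is chosen because it matches
the worked chain example (−1, −0.5, −0.25) and converges, for spectral
radius < 1, to the analytic fixed point with the knockout held at zero.
Simulated expression is floored at zero by default ("nonneg"); clamping to
the observed per-gene range is available, matching the reference tool's
behaviour.

Knockout cells are classified by 50-NN plurality vote in the shared
principal subspace; vote fractions are the label probabilities, ties go to
the lowest cluster label (determinism over unspecified behaviour), and
embedding positions are neighbour means. Cluster abundance uses a
quasi-Poisson log-link GLM: per replicate and cluster the response is the
summed label probability × k, rounded (so probabilistic assignments become
integers), with `log(replicate total)` as offset and genotype (+ batch) as
covariates; the CI is ±1.96·SE with the Pearson-dispersion scaling. When a
genotype has no cells in a cluster the fold change diverges; the package
returns `NA` with a flag instead of a number. Clusters under 100
(probability-weighted) cells are flagged as unreliable.

The CI-calibration harness (`simulate_abundance_null()`) draws replicate
totals ~Poisson(400) and focal-cluster counts ~Poisson(0.25 × total) — a
genuinely null genotype effect — across 64 replicates per genotype and two
batches. The depth of that design is deliberate: the Wald interval's true
coverage is approximately `P(|t_df| ≤ 1.96)`, i.e. 94.0% at 30 residual
degrees of freedom and 94.8% at ~125, so a deep design is needed before
"95% interval" is an honest description. At the experiment's own scale
(four samples, one residual degree of freedom) these asymptotics do not
hold, which is worth remembering when reading such intervals in any study
of this design.

Staging: pseudotime ranks are split into 20 contiguous equal-count bins
(sizes differing by at most one; ties broken by stable input order).
Dynamic genes pass `log2(max period mean + 1) − log2(min period mean + 1)
> 0.75` (ε = 1 because pseudobulk period means are often zero) with a
BH-adjusted Kruskal–Wallis q-value < 0.01 across 20 periods — the original
screen's internals are unpublished, so a rank-based one-way test is the
package's choice and is pluggable. Genotype and bin pseudobulks (raw-count
sums) are rank-transformed over the dynamic set and correlated (Pearson on
ranks); the two best bins per genotype are reported. Rank transformation
makes staging invariant to any monotone per-profile distortion of counts.

## The synthetic data, and what the tests do and do not show

The generators emulate the *statistical structure* the pipeline assumes:
Poisson UMI counts with log-normal library sizes and per-sample log-normal
batch factors (2/3/3/2 replicate structure), a three-phase cell-cycle
label with expression offsets, Beta-distributed mitochondrial fractions,
planted contaminant clusters and exact planted QC violations; capped
(≤ 4) Poisson insertion counts over non-overlapping 501 bp peaks with
promoter geometry and Bernoulli motif hits; stable linear ground-truth GRNs
(`x = baseline + (I − W')⁻¹ ε`) with log-normal baselines; and a
log-linear monotone trajectory. Planting is exact where rules are tested
(mitochondria, haemoglobin, contaminant flags) and margin-based where a
Poisson realization intervenes (low-depth cells are generated at expected
depth ~1000 against a ≥ 3000 floor for everyone else, so crossing the 2000
boundary has negligible probability under any seed).

What passing tests show: the accounting, algebra and statistical behaviour
of every stage are correct on data satisfying each stage's assumptions.
What they do not show: robustness to the things real data add — ambient
RNA, doublet structure beyond planted fractions, non-linear regulation,
read-level artefacts, mappability and peak-calling noise. Scale is also
deliberately reduced (hundreds-to-thousands of cells and peaks, tens of
genes per network) so the full suite runs in minutes; the QC replays run at
the published cell counts because the ledger arithmetic is exact at any
scale.

## Known limitations

- Louvain/UMAP internals, CCA integration, tree-ensemble importance
  estimation, PWM scanning and ontology enrichment are out of scope; motif
  hits, pseudotime orderings and cluster labels enter as inputs, and the
  smoothing used before GRN fitting is a plain k-NN average rather than a
  balanced-kNN imputation.
- The gene-score approximation for scATAC (gene body + distance-weighted
  distal signal) is not included; τ, deviations and co-accessibility operate
  directly on the peak matrix.
- The MP retention rule and the bag-level t-test have the finite-size
  calibration properties described above; both are implemented exactly as
  specified, and their behaviour is measured, not hidden.
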