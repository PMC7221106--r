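---
title: "Models and methods in scCochlea"
author: "scCochlea authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in scCochlea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`scCochlea` reimplements a single-cell analysis workflow for the
developing cochlear epithelium as a set of tested, composable functions.
This vignette describes the statistical models behind each stage, the
tunable parameters and their defaults, what the synthetic generator does
and does not emulate, and the design choices made where the procedure was
genuinely open.

## The QC cascade

Cells are filtered on five bounds: fewer than 200 detected genes, fewer
than 1,500 UMI, more than 3,000 detected genes, more than 15,000 UMI, more
than 5% mitochondrial UMI, or more than 5% stress-gene UMI; genes must be
detected in at least 10 cells. A cell is excluded when **any** single
bound is violated. The low/high bounds are often written as pairs
("<200 genes and 1,500 UMI"), which is grammatically ambiguous between a
conjunctive and a disjunctive reading; exclusion-on-any-violation is the
common practice that phrasing abbreviates, and the conjunctive reading
remains available through `qc_thresholds(conjunctive = TRUE)`.
Mitochondrial and stress fractions are defined as UMI shares rather than
gene-count shares — the standard convention. Because no canonical stress
signature is published for this tissue, stress genes are identified by the
`stress-` name prefix or supplied explicitly; the same convention (`mt-`)
applies to mitochondrial genes.

## Normalization, covariate regression, scaling

Expression is depth-normalized to 10,000 counts per cell and
log-transformed (`log1p`). Per gene, total UMI, mitochondrial fraction and
stress fraction are regressed out by ordinary least squares and the
residuals are centered, scaled to unit variance, and clipped at ±10
(clipping bounds the influence of single outlier cells on the PCA; the
value is the customary one). Batch alignment by canonical correlation is
out of scope; the linear covariate regression is the declared
replacement, and the generator can plant additive batch shifts to exercise
it.

### Variable-gene selection

PCA is computed on the 500 most variable genes, ranked by the residual of
a loess fit (span 0.3) of log dispersion (variance/mean of the normalized
counts) on log mean. This step matters quantitatively: with ~2,000 genes
of which only a few hundred carry the cell-type programs, full-matrix PCA
leaves the program directions below the Marchenko–Pastur noise edge of the
sample covariance spectrum, and no downstream method can recover them.
Restricting the scaled matrix to trend-exceeding genes lifts the planted
structure far above the noise floor. The mean–dispersion trend is fitted
rather than binned because, for negative binomial counts of a common
inverse-dispersion, variance/mean grows smoothly with the mean; a binned
z-score lets high-mean background genes swamp genuinely overdispersed
ones within a bin.

## Clustering and resolution selection

Cells are embedded with PCA (20 components, eigendecomposition of the
smaller Gram matrix; component signs fixed so the largest-magnitude gene
loading is positive). A shared-nearest-neighbor graph (k = 20, Jaccard
weights, pruned below 1/15) is clustered by Louvain modularity at each
resolution of the grid 0.2–2.4 in 0.2 steps. Each partition is scored by
the out-of-bag misclassification rate of a 100-tree random forest
predicting labels from the embedding; a single-cluster partition is
defined to have OOB error 0 (there is nothing to misclassify).

"Low OOB error and high cluster number" is not an algorithm, so the
selection rule is made explicit: among partitions whose OOB error is
within `selectionTolerance = 0.05` of the minimum, take the one with the
most clusters, breaking ties toward the lower resolution. The tolerance is
the smallest band that tolerates Monte-Carlo noise in the OOB estimate
while still rejecting over-clusterings: splitting one homogeneous
100-cell group in a 1,400-cell dataset costs about 0.03–0.07 OOB, so
genuine over-splits fall outside the band while resolution-stable
partitions stay inside it.

## Pseudotime and phase modules

A minimum spanning tree is built over cluster centroids in the embedding;
cells are projected onto their nearest tree edge and pseudotime is the
normalized arc length from the root cluster's centroid. The root is given
explicitly or chosen as the cluster with the highest mean expression of a
progenitor marker set. This MST-plus-projection construction, followed by
a principal-curve refinement (each embedding coordinate smoothed against
pseudotime by lowess with a coarse-to-fine span schedule 0.5 → 0.2 over 4
iterations, cells re-projected onto the fitted curve each pass), is the
declared substitute for tree-learning dimensionality-reduction methods:
it preserves the tested contract — ordering fidelity and at most one
bifurcation — and every step of it can be verified directly. The
coarse-to-fine schedule matters: a tight span on the first pass can fold
the fitted curve back on itself at the ends and scramble the ordering
there. Single leaf centroids hanging directly off a branch node are
pruned as over-clustering spurs before branch calling; a genuine branch
must be supported by at least two centroids. Refinement is skipped when a
bifurcation is present (a single curve cannot represent a Y), so branched
trajectories keep the piecewise-linear ordering.

Genes varying along pseudotime are tested per gene by an F test of a
natural cubic spline fit (3 internal knots at pseudotime quantiles)
against an intercept-only model, on the log-normalized values, with
Benjamini–Hochberg control at FDR 0.1. The Gaussian working model on
log-normalized values replaces a count-model likelihood ratio test; the
substitution is justified because all downstream claims are rank- and
recovery-based, and the test's null calibration is verified empirically
in the suite (type-I error at nominal level on simulated null counts).

Significant genes are clustered into phase modules. Each gene's z-scored
expression is smoothed with the same spline basis and evaluated on a
50-point grid, giving a trend curve in per-gene SD units. Genes whose
curve spans at least `minAmplitude = 1` SD drive a seeded k-means on the
unit-scaled curve shapes, with `k = "auto"` chosen in 2..8 by mean
silhouette; the remaining significant genes are assigned to the nearest
module centroid afterwards, so every significant gene carries exactly one
module id. The amplitude gate exists because an FDR-0.1 discovery set
necessarily contains roughly 10% null genes; their fitted trends are flat,
and unit-scaling a flat curve amplifies estimation noise into a
full-amplitude random shape. Left in, those genes form spurious extra
clusters and any unsupervised choice of k (mean silhouette and the gap
statistic both, in our experiments) tracks them upward; gated out of the
k-selection, the four planted temporal families are recovered as exactly
four modules. Modules are relabeled by the position of their peak, so
`module1` peaks earliest.

## Regulons

Pseudocells average 5–20 same-type cells (50 pseudocells per type by
default); pooling suppresses drop-out noise before rank statistics.
Regulon inference is by Spearman correlation of each TF with all genes
across pseudocells (threshold 0.3, at most 50 targets); cis-regulatory
motif pruning requires external motif databases and is out of scope, so
curated regulons can be supplied as a GMT instead. The regulon activity
score of a pseudocell is the area under the recovery curve of the
regulon's genes within the top `topFraction = 0.05` of the expression
ranking (ties broken by gene name), normalized by the maximal achievable
area so that RAS lies in [0, 1] — 0.05 is the customary recovery-curve
cutoff. The regulon specificity score for a cell type is
`1 − sqrt(JSD(p_R, p_C))` with base-2 logarithms, where `p_R` is the RAS
vector normalized to a distribution over pseudocells and `p_C` the
normalized indicator of the type; base 2 bounds the divergence in [0, 1]
and hence the score. The implementation is checked against a direct
entropy summation to 1e-12 in the test suite.

## Metabolic regulation matrix and disease maps

For each pathway and cell type, genes are tested between the two time
points by the Wilcoxon rank-sum test with no detection or fold-change
gates; `U` counts genes with positive average log fold change at raw
p < 0.05 and `D` the negative ones. Raw rather than adjusted p is used
here deliberately — it is the printed criterion for this statistic, while
the surrounding marker analyses use adjusted p < 0.05 as printed there.
The per-pathway frequencies `p(U) = U/(U+D)` and `p(D) = D/(U+D)` are
undefined at `U+D = 0`; such pathways are dropped (NA) from the
normalization, which preserves the identities the construction implies:
each type's `P^U` sums to exactly 1 and the matrix column sums to 0.
Exchanging the time points swaps U and D and negates the matrix exactly;
the suite asserts this antisymmetry.

Disease-gene localization maps are cluster-averaged z-scores: per gene,
z-score across all cells, then mean within cluster, one matrix per disease
class, with genes absent from the matrix listed separately. The packaged
GMT files are synthetic stand-ins whose names match the generator presets;
they demonstrate the format and are not curated gene lists.

## The synthetic generator

Counts are negative binomial with gene-level means and a cell-level
library-size factor: a background gene's mean is drawn from an exponential
with mean `baseMean` (the low tail exercises the 10-cell gene filter),
planted genes (markers, exclusives, module genes, regulon genes, pathway
genes) sit at `baseMean` exactly so their detectability is controlled, and
the factor is log-normal (sd 0.2) truncated to [0.6, 1.8]. The truncation
is part of the generator's contract: ordinary cells must land inside the
QC depth window, so that the planted violators are the *only* violators
and QC recovery can be asserted exactly. The NB inverse-dispersion
(`size`) defaults to 2, a typical droplet-UMI value.

Per structure:

* **Cell-type programs** — disjoint marker sets per type, mean multiplied
  by `markerFold = 6` in the own type. The presets plant 25 markers per
  type, matching the scale on which real cluster tables are drawn (a
  top-25 table per cluster), and 5 exclusive genes per type (near-silent
  elsewhere, NB mean 0.02) for the exclusivity screen.
* **QC violators** — designated cells are corrupted to violate exactly one
  rule. With 2,000-gene matrices a cell cannot exceed 3,000 detected
  genes, so the high-complexity rule is planted through its paired depth
  bound (UMI above 15,000).
* **Trajectory** — pseudotime uniform on [0, 1]; four template shapes
  (early-decreasing, transient peak, mid-rising sigmoid, late-rising
  power) multiply module-gene means by up to `markerFold`, mirroring the
  four phases of outer-hair-cell development. The preset plants 50 genes
  per module, the scale at which trajectory screens of real data report
  significant genes.
* **Regulons** — within a TF's active type, the TF and its targets share a
  per-cell exponential latent activity and counts are Poisson given the
  factor, so the factor itself carries the overdispersion. This makes
  `couplingStrength` map directly onto TF–target correlation: pure NB
  noise on top of a shared mean would cap the correlation near 0.5
  regardless of coupling.
* **Time points** — the second dataset multiplies a planted fraction of
  each pathway's gene means by `exp(±log 2)`; the exact up/down counts are
  recorded.

What the generator does **not** emulate: ambient RNA, doublets,
cell-cycle structure, batch chemistry differences, realistic gene-gene
correlation beyond the planted factors, or the empirical library-size and
dispersion distributions of any particular tissue (no public figures exist
to calibrate them for this one). Passing recovery tests therefore show the
pipeline's statistics are implemented correctly and are well-calibrated
under clean NB assumptions — not that the pipeline is robust to every
artifact of real droplet data.

## Problem sizes and numerical choices

The packaged presets are desk-scale by design: `p1` (15 types, ~1,500
cells × 2,000 genes), `p7` (12 types, ~1,200 cells), `trajectory` (400
cells, 4 × 50 module genes), `regulons` (3 TFs in 360 cells), `timepoints`
(6 pathways × 16 genes, 450 cells per time point). These sizes keep a full
10-seed recovery experiment to roughly a minute per preset while leaving
every statistic in its asymptotic regime (group sizes ≥ 100 for the
rank tests, ≥ 50 pseudocells per type).

Other numerical choices: PCA rank deficiencies are truncated with a
warning; collinear covariates are dropped with a warning; zero-variance
genes become all-zero rows in scaled and z-score matrices (with a
warning) rather than NaN; Wilcoxon p-values use the normal approximation
with continuity correction; Bonferroni is used for marker tables (the
historical default of the workflow this mirrors) and Benjamini–Hochberg
where an FDR is specified; k-means uses 10 restarts under a fixed seed;
ties in expression rankings break by gene name so every ranking is
deterministic.

## Known limitations

* The OOB selection rule assumes over-clustering raises OOB error by at
  least the tolerance; for very small clusters (tens of cells) the OOB
  estimate is noisy and the band may admit an over-split partition.
* `order_cells` supports at most one bifurcation; more complex topologies
  are rejected rather than approximated. Pseudotime refinement is skipped
  on branched trees.
* Regulon inference is co-expression only; without motif pruning,
  correlated non-targets can enter a regulon, and the "significance" of a
  regulon is not tested — scores are descriptive and rank-based.
* The regulation matrix treats pathways independently; shared genes
  between pathways are counted in each.
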