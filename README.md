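# scCochlea

Single-cell RNA-seq analysis pipeline for the developing cochlear
epithelium, with a synthetic data generator that plants full ground truth.

## The problem

The mouse cochlear floor epithelium between E14 and P7 contains a dozen or
more transcriptionally distinct cell populations — inner and outer hair
cells, several supporting-cell types, Kölliker's organ cells, lateral
progenitors — whose identities, differentiation trajectories and metabolic
states can be read out from droplet scRNA-seq. Analyzing such data takes a
chain of statistical procedures: QC filtering, depth normalization with
nuisance-covariate regression, graph-based clustering with a principled
choice of the resolution parameter, marker and exclusive-gene screens,
pseudotime ordering with temporal gene-module discovery, regulon
(TF + targets) specificity scoring, and a pathway-level summary of
metabolic shifts between time points. `scCochlea` implements that chain as
tested, reusable R functions, and ships a negative-binomial count
generator that emulates each structure (cell-type programs, QC violators,
a differentiation continuum, TF-coupled co-expression, two-time-point
pathway shifts) with planted ground truth, so every stage can be validated
by recovery instead of by eye.

## The statistics at the core

* **Resolution selection by OOB error.** Cells are clustered on a
  shared-nearest-neighbor graph by modularity (Louvain) at resolutions
  0.2–2.4 in 0.2 steps. Each partition is scored by the out-of-bag
  misclassification rate of a bagged-tree ensemble (random forest)
  predicting the labels from the PCA embedding. Among partitions with OOB
  error within 0.05 of the minimum, the one with the most clusters is
  selected ("low OOB error and high cluster number").
* **Phase modules along pseudotime.** Cells are ordered on a minimum
  spanning tree over cluster centroids, refined by a principal-curve pass.
  Genes varying along pseudotime are found by a spline-vs-intercept F test
  at FDR 0.1 (Benjamini–Hochberg); significant gene trends are smoothed on
  a 50-point grid and k-means-partitioned into phase modules, with k
  chosen by mean silhouette over genes whose trend has real amplitude.
* **Regulon specificity (RSS).** Expression is pooled into pseudocells of
  5–20 same-type cells; a regulon's activity (RAS) per pseudocell is the
  normalized area under the recovery curve of its targets in the top 5% of
  the expression ranking; its specificity for a cell type is
  `RSS = 1 − sqrt(JSD(p_R, p_C))`, the Jensen–Shannon divergence (log base
  2) between the normalized activity distribution and the cell-type
  indicator.
* **Metabolic regulation matrix.** For each pathway *n* and cell type,
  genes DE between two time points (Wilcoxon, raw p < 0.05) are counted as
  up (*U_n*) or down (*D_n*); `p(U_n) = U_n / (U_n + D_n)` and likewise
  `p(D_n)`; the vectors *P^U* and *P^D* are each normalized to sum 1 over
  pathways and the matrix entry is *P^U − P^D* (positive = up-shift,
  negative = down-shift).

## Worked example

```r
library(scCochlea)

ds <- generate_preset_dataset("p1", seed = 1)   # 15 planted programs
cp <- cluster_pipeline(ds$counts, pipeline_config(seed = 1))
cp$scan
adjusted_rand_index(cp$labels, ds$cellType[names(cp$labels)])
```

```
LabeledDataset: 2000 genes x 1500 cells, 15 cell type(s)
[qc] 1410/1500 cells retained, 1996 genes (seed 1)
[cluster] selected 15 clusters at resolution 0.20 (seed 1)
ResolutionScan:
 resolution nClusters oobError
        0.2        15        0
        ...
        2.4        15        0
selected: resolution 0.20 with 15 clusters (OOB 0.000)
[1] 1
```

The QC stage removed exactly the 90 planted violators (low-complexity,
over-deep, high-mito and high-stress cells); the scan found the 15 planted
expression programs at every resolution with OOB error 0 (the programs are
well separated), and the selected labels match the planted types exactly
(adjusted Rand index 1). Marker tables follow:

```r
rec <- find_all_markers(cp$expr, cp$labels)
head(top_markers(rec, 3)[, c("gene", "cluster", "avgLogFC", "pctIn", "pctOut", "adjP")])
```

```
             gene cluster avgLogFC     pctIn    pctOut         adjP
1.27 marker-06-09       1 1.939187 0.9795918 0.6592988 1.005018e-45
1.40 marker-06-22       1 1.923816 0.9897959 0.6669207 8.183923e-47
...
```

`avgLogFC` is the natural-log mean difference on the log-normalized
scale; `pctIn`/`pctOut` are detection fractions inside/outside the
cluster; `adjP` is Bonferroni-adjusted. The planted markers of the type
forming cluster 1 top its table, as they should.

A command-line front end covers the same stages
(`simulate`, `qc`, `cluster`, `markers`, `trajectory`, `regulons`,
`metabolic`, `disease-map`, `all`):

```sh
Rscript exec/sccochlea simulate --preset p1 --seed 1 --out sim/
Rscript exec/sccochlea cluster --input sim/ --seed 1 --out results/
```

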