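#' Two-group differential expression (Wilcoxon)
#'
#' One comparison of two disjoint cell groups on log-normalized expression.
#' Genes are pre-filtered to those detected in at least `minPct` of either
#' group and with `|avgLogFC| >= logfcThreshold`; the test is a two-sided
#' Wilcoxon rank-sum, Bonferroni-adjusted over the genes actually tested.
#' `avgLogFC` is the natural-log mean difference of the log-normalized
#' values (group A minus group B); set `log2fc = TRUE` for log2 units.
#'
#' @param expr Genes-by-cells log-normalized matrix.
#' @param cellsA,cellsB Disjoint character/index vectors of cells (>= 3 each).
#' @param minPct Detection-fraction gate (default 0.25).
#' @param logfcThreshold Fold-change gate on `|avgLogFC|` (default 0.25).
#' @param log2fc Report fold changes in log2 instead of natural log.
#' @return Data frame of `MarkerRecord`s: gene, avgLogFC, pctIn, pctOut,
#'   pValue, adjP, ordered by pValue.
#' @export
de_two_groups <- function(expr, cellsA, cellsB, minPct = 0.25,
                          logfcThreshold = 0.25, log2fc = FALSE) {
  if (length(cellsA) < 3L || length(cellsB) < 3L) {
    stop("both groups need at least 3 cells", call. = FALSE)
  }
  A <- as.matrix(expr[, cellsA, drop = FALSE])
  B <- as.matrix(expr[, cellsB, drop = FALSE])
  pctIn <- rowMeans(A > 0)
  pctOut <- rowMeans(B > 0)
  lfc <- rowMeans(A) - rowMeans(B)
  if (log2fc) lfc <- lfc / log(2)
  keep <- pmax(pctIn, pctOut) >= minPct & abs(lfc) >= logfcThreshold
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(data.frame(gene = character(0), avgLogFC = numeric(0),
                      pctIn = numeric(0), pctOut = numeric(0),
                      pValue = numeric(0), adjP = numeric(0)))
  }
  p <- vapply(idx, function(i) {
    stats::wilcox.test(A[i, ], B[i, ], exact = FALSE)$p.value
  }, numeric(1))
  out <- data.frame(gene = rownames(expr)[idx], avgLogFC = lfc[idx],
                    pctIn = pctIn[idx], pctOut = pctOut[idx],
                    pValue = p,
                    adjP = stats::p.adjust(p, method = "bonferroni"),
                    row.names = NULL)
  out[order(out$pValue, out$gene), , drop = FALSE]
}

#' One-vs-rest markers for every cluster
#'
#' Runs [de_two_groups()] of each cluster against all remaining cells and
#' stacks the records with a `cluster` column; `positive` flags records
#' with `avgLogFC > 0` (enriched in the cluster).
#'
#' @inheritParams de_two_groups
#' @param labels Cluster label per cell (aligned with `colnames(expr)`).
#' @return Data frame of marker records across clusters.
#' @export
find_all_markers <- function(expr, labels, minPct = 0.25,
                             logfcThreshold = 0.25, log2fc = FALSE) {
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) < 2L) stop("need at least 2 clusters", call. = FALSE)
  cells <- colnames(expr)
  do.call(rbind, lapply(lev, function(cl) {
    rec <- de_two_groups(expr, cells[labels == cl], cells[labels != cl],
                         minPct, logfcThreshold, log2fc)
    if (nrow(rec) == 0L) return(NULL)
    rec$cluster <- cl
    rec$positive <- rec$avgLogFC > 0
    rec
  }))
}

#' Top markers per cluster
#'
#' Per cluster, the top `n` positive records ordered by decreasing
#' `avgLogFC`, ties broken by adjusted p then gene name.
#'
#' @param records Output of [find_all_markers()].
#' @param n Records per cluster (default 25).
#' @return Row-subset data frame.
#' @export
top_markers <- function(records, n = 25L) {
  stopifnot(n >= 1)
  pos <- records[records$positive, , drop = FALSE]
  do.call(rbind, lapply(split(pos, pos$cluster), function(d) {
    d <- d[order(-d$avgLogFC, d$adjP, d$gene), , drop = FALSE]
    utils::head(d, n)
  }))
}

#' Exclusive-expression screen
#'
#' Genes detected in at least `fOn` of the target cluster's cells and in at
#' most `fOff` of the cells of every other cluster.
#'
#' @param expr Genes-by-cells log-normalized matrix.
#' @param labels Cluster label per cell.
#' @param targetCluster Cluster to screen for.
#' @param fOn,fOff Detection-fraction gates (defaults 0.3 / 0.1).
#' @return Character vector of exclusive genes (possibly empty).
#' @export
exclusive_genes <- function(expr, labels, targetCluster, fOn = 0.3,
                            fOff = 0.1) {
  labels <- as.character(labels)
  if (!targetCluster %in% labels) {
    stop("targetCluster not present: ", targetCluster, call. = FALSE)
  }
  det <- expr > 0
  inFrac <- rowMeans(det[, labels == targetCluster, drop = FALSE])
  others <- setdiff(unique(labels), targetCluster)
  offMax <- rep(0, nrow(expr))
  for (cl in others) {
    offMax <- pmax(offMax, rowMeans(det[, labels == cl, drop = FALSE]))
  }
  rownames(expr)[inFrac >= fOn & offMax <= fOff]
}

#' Cluster-averaged z-score matrix
#'
#' Per gene, z-scores across all cells, then averaged within each cluster;
#' the form used for the heat maps of cell-type-restricted expression.
#' Zero-variance genes yield all-zero rows with a warning.
#'
#' @param expr Genes-by-cells log-normalized matrix.
#' @param labels Cluster label per cell.
#' @param genes Genes to include (subset of `rownames(expr)`).
#' @return Matrix genes x clusters of mean z-scores.
#' @export
celltype_zscore_matrix <- function(expr, labels, genes = rownames(expr)) {
  miss <- setdiff(genes, rownames(expr))
  if (length(miss)) stop("genes absent from matrix: ",
                         paste(utils::head(miss), collapse = ", "),
                         call. = FALSE)
  labels <- as.character(labels)
  sub <- as.matrix(expr[genes, , drop = FALSE])
  mu <- rowMeans(sub)
  sdev <- apply(sub, 1L, stats::sd)
  zeroVar <- sdev < 1e-12
  if (any(zeroVar)) {
    warning("zero-variance gene(s) set to zero rows: ",
            paste(utils::head(genes[zeroVar]), collapse = ", "))
    sdev[zeroVar] <- 1
  }
  z <- (sub - mu) / sdev
  z[zeroVar, ] <- 0
  lev <- sort(unique(labels))
  out <- vapply(lev, function(cl) {
    rowMeans(z[, labels == cl, drop = FALSE])
  }, numeric(nrow(z)))
  out <- matrix(out, nrow = nrow(z), dimnames = list(genes, lev))
  out
}

#' Cross-dataset direction concordance
#'
#' Compares the direction of differential expression with an independent
#' reference profiled for the same two cell classes. A DE gene is eligible
#' if the reference fold change (pseudocount 1 on both means) clears
#' `foldThreshold`; it is concordant if the reference direction matches the
#' DE direction. Genes absent from the reference are counted separately.
#'
#' @param records Data frame of DE records (gene, avgLogFC).
#' @param refMeansA,refMeansB Named nonnegative reference mean expression
#'   for the class matching positive / negative `avgLogFC` respectively.
#' @param foldThreshold Reference fold-change threshold (default 2).
#' @return A `ConcordanceResult` list: nEligible, nConcordant, fraction,
#'   foldThreshold, notDetected (genes missing from the reference).
#' @export
cross_dataset_concordance <- function(records, refMeansA, refMeansB,
                                      foldThreshold = 2) {
  stopifnot(all(refMeansA >= 0), all(refMeansB >= 0))
  common <- intersect(records$gene, intersect(names(refMeansA),
                                              names(refMeansB)))
  notDetected <- setdiff(records$gene, common)
  rec <- records[records$gene %in% common, , drop = FALSE]
  fold <- (refMeansA[rec$gene] + 1) / (refMeansB[rec$gene] + 1)
  eligible <- fold >= foldThreshold | fold <= 1 / foldThreshold
  concordant <- eligible & (sign(log(fold)) == sign(rec$avgLogFC))
  nE <- sum(eligible)
  structure(list(nEligible = nE, nConcordant = sum(concordant),
                 fraction = if (nE > 0) sum(concordant) / nE else NA_real_,
                 foldThreshold = foldThreshold, notDetected = notDetected),
            class = "ConcordanceResult")
}

#' @export
print.ConcordanceResult <- function(x, ...) {
  cat(sprintf(
    "ConcordanceResult: %d/%d eligible genes concordant (%.1f%%) at %g-fold\n",
    x$nConcordant, x$nEligible, 100 * x$fraction, x$foldThreshold))
  if (length(x$notDetected)) {
    cat(sprintf("  %d gene(s) not detected in reference\n",
                length(x$notDetected)))
  }
  invisible(x)
}
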