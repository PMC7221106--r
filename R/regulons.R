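#' Pool cells into pseudocells
#'
#' Per cell type, draws `nPerType` random subsets of size uniform in
#' `[poolMin, poolMax]` (without replacement within a subset) and averages
#' their expression. Pooling stabilizes downstream regulon scoring. Types
#' with fewer than `poolMin` cells are skipped with a warning.
#'
#' @param expr Genes-by-cells matrix (counts or normalized expression).
#' @param labels Cell-type label per cell.
#' @param poolMin,poolMax Pool-size bounds (defaults 5 and 20).
#' @param nPerType Pseudocells per type (default 50).
#' @param seed Integer seed.
#' @return A `PseudocellMatrix`: `expr` (genes x pseudocells), `cellType`
#'   and `memberCount` per pseudocell.
#' @export
make_pseudocells <- function(expr, labels, poolMin = 5L, poolMax = 20L,
                             nPerType = 50L, seed = 1L) {
  stopifnot(poolMin >= 1L, poolMin <= poolMax)
  if (nPerType <= 0L) stop("nPerType must be positive", call. = FALSE)
  labels <- as.character(labels)
  expr <- as.matrix(expr)
  lev <- sort(unique(labels))
  set.seed(seed)
  cols <- list()
  type <- character(0)
  size <- integer(0)
  for (cl in lev) {
    idx <- which(labels == cl)
    if (length(idx) < poolMin) {
      warning(sprintf("type %s has %d (< %d) cells; skipped",
                      cl, length(idx), poolMin))
      next
    }
    for (j in seq_len(nPerType)) {
      m <- sample(poolMin:min(poolMax, length(idx)), 1L)
      members <- sample(idx, m)
      cols[[length(cols) + 1L]] <- rowMeans(expr[, members, drop = FALSE])
      type <- c(type, cl)
      size <- c(size, m)
    }
  }
  if (length(cols) == 0L) stop("no type had enough cells to pool",
                               call. = FALSE)
  pcExpr <- do.call(cbind, cols)
  colnames(pcExpr) <- sprintf("pc%04d", seq_len(ncol(pcExpr)))
  structure(list(expr = pcExpr, cellType = type, memberCount = size),
            class = "PseudocellMatrix")
}

#' @export
print.PseudocellMatrix <- function(x, ...) {
  cat(sprintf("PseudocellMatrix: %d genes x %d pseudocells (%d types)\n",
              nrow(x$expr), ncol(x$expr), length(unique(x$cellType))))
  invisible(x)
}

#' Infer co-expression regulons
#'
#' For each transcription factor, targets are the genes whose Spearman
#' correlation with the TF across pseudocells reaches `corrThreshold`,
#' capped at `maxTargets` by descending correlation. TFs with no targets
#' are dropped. (Cis-regulatory motif pruning is outside this package's
#' scope; curated regulons can be supplied as a GMT instead.)
#'
#' @param pc A [make_pseudocells()] result.
#' @param tfList Character vector of TF gene names (subset of the matrix).
#' @param corrThreshold Spearman threshold (default 0.3).
#' @param maxTargets Cap on targets per regulon (default 50).
#' @return List of `Regulon`s: `tf`, `targets`, `weights` (correlations).
#' @export
infer_regulons <- function(pc, tfList, corrThreshold = 0.3,
                           maxTargets = 50L) {
  stopifnot(all(tfList %in% rownames(pc$expr)))
  R <- stats::cor(t(pc$expr[tfList, , drop = FALSE]), t(pc$expr),
                  method = "spearman")
  regs <- lapply(tfList, function(tf) {
    r <- R[tf, ]
    r <- r[names(r) != tf & !is.na(r) & r >= corrThreshold]
    if (length(r) == 0L) return(NULL)
    r <- r[order(-r, names(r))]
    r <- utils::head(r, maxTargets)
    structure(list(tf = tf, targets = names(r), weights = unname(r)),
              class = "Regulon")
  })
  names(regs) <- tfList
  regs[!vapply(regs, is.null, logical(1))]
}

#' Regulon activity score (RAS)
#'
#' Per pseudocell, genes are ranked by descending expression (ties broken
#' by gene name) and the RAS is the area under the recovery curve of the
#' regulon's targets within the top `ceiling(topFraction * nGenes)` ranks,
#' normalized by the maximal achievable area, so RAS lies in `[0, 1]`.
#'
#' @param pc A `PseudocellMatrix`.
#' @param regulon A `Regulon` (or list with `tf`, `targets`).
#' @param topFraction Fraction of the ranking examined (default 0.05).
#' @return Named RAS vector over pseudocells.
#' @export
regulon_activity <- function(pc, regulon, topFraction = 0.05) {
  stopifnot(topFraction > 0, topFraction < 1)
  genes <- c(regulon$tf, regulon$targets)
  genes <- intersect(genes, rownames(pc$expr))
  if (length(genes) == 0L) stop("empty regulon", call. = FALSE)
  nGenes <- nrow(pc$expr)
  maxRank <- ceiling(topFraction * nGenes)
  nT <- length(genes)
  maxAUC <- if (nT >= maxRank) maxRank * (maxRank + 1) / 2 else
    nT * (nT + 1) / 2 + (maxRank - nT) * nT
  gname <- rownames(pc$expr)
  apply(pc$expr, 2L, function(x) {
    ranks <- order(-x, gname)
    pos <- match(genes, gname[ranks])
    pos <- pos[pos <= maxRank]
    sum(maxRank - pos + 1) / maxAUC
  })
}

# Jensen-Shannon divergence in log base 2 (0 * log 0 == 0)
.jsd2 <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

#' Regulon specificity score (RSS)
#'
#' Converts a RAS vector into a specificity score for one cell type:
#' `RSS = 1 - sqrt(JSD(p_R, p_C))`, where `p_R` is the RAS vector
#' normalized to sum 1 over pseudocells, `p_C` the normalized indicator of
#' the target type, and JSD the Jensen-Shannon divergence in log base 2
#' (bounded in `[0, 1]`, so RSS is too). RSS is 1 when activity is uniform
#' over exactly the target type's pseudocells, 0 when the supports are
#' disjoint.
#'
#' @param ras RAS vector over pseudocells (not all zero).
#' @param pseudocellTypes Cell-type label per pseudocell.
#' @param targetType The type scored for.
#' @return RSS in `[0, 1]`.
#' @export
regulon_specificity <- function(ras, pseudocellTypes, targetType) {
  if (all(ras == 0)) stop("RAS is all zero", call. = FALSE)
  stopifnot(length(ras) == length(pseudocellTypes),
            targetType %in% pseudocellTypes)
  pR <- ras / sum(ras)
  ind <- as.numeric(pseudocellTypes == targetType)
  pC <- ind / sum(ind)
  1 - sqrt(.jsd2(pR, pC))
}

#' RAS and RSS matrices for a regulon list
#'
#' @param pc A `PseudocellMatrix`.
#' @param regulons List of `Regulon`s (or a named list of gene vectors, in
#'   which case each set is treated as `tf = NULL` targets).
#' @param topFraction Passed to [regulon_activity()].
#' @return A `RegulonScores`: `RAS` (regulon x pseudocell), `RSS`
#'   (regulon x cell type), `pseudocellTypes`.
#' @export
regulon_scores <- function(pc, regulons, topFraction = 0.05) {
  regs <- lapply(seq_along(regulons), function(i) {
    r <- regulons[[i]]
    if (!inherits(r, "Regulon")) r <- list(tf = NULL, targets = r)
    r
  })
  nms <- names(regulons)
  if (is.null(nms)) nms <- vapply(regs, `[[`, "", "tf")
  RAS <- t(vapply(regs, function(r) regulon_activity(pc, r, topFraction),
                  numeric(ncol(pc$expr))))
  rownames(RAS) <- nms
  types <- sort(unique(pc$cellType))
  RSS <- vapply(types, function(tt) {
    apply(RAS, 1L, function(ras) {
      if (all(ras == 0)) NA_real_ else
        regulon_specificity(ras, pc$cellType, tt)
    })
  }, numeric(nrow(RAS)))
  RSS <- matrix(RSS, nrow = nrow(RAS), dimnames = list(nms, types))
  structure(list(RAS = RAS, RSS = RSS, pseudocellTypes = pc$cellType),
            class = "RegulonScores")
}

#' @export
print.RegulonScores <- function(x, ...) {
  cat(sprintf("RegulonScores: %d regulons x %d pseudocells; %d cell types\n",
              nrow(x$RAS), ncol(x$RAS), ncol(x$RSS)))
  invisible(x)
}

#' Rank regulons by specificity for one cell type
#'
#' @param scores A `RegulonScores` (or an RSS matrix).
#' @param cellType Column to rank by.
#' @return Data frame (regulon, rss) in descending RSS, ties by name.
#' @export
rank_regulons <- function(scores, cellType) {
  rss <- if (inherits(scores, "RegulonScores")) scores$RSS else scores
  stopifnot(cellType %in% colnames(rss))
  v <- rss[, cellType]
  ord <- order(-v, rownames(rss))
  data.frame(regulon = rownames(rss)[ord], rss = unname(v[ord]),
             row.names = NULL)
}
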