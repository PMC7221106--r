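#' Pathway up/down DE counts between two time points
#'
#' For one cell type, tests every gene of a pathway between the two
#' time-point expression matrices (Wilcoxon, no detection or fold-change
#' gates) and counts genes upregulated at the later time point
#' (`avgLogFC > 0`, raw `p < 0.05`) and downregulated (`avgLogFC < 0`,
#' raw `p < 0.05`). Pathway genes absent from either matrix are skipped
#' with a warning.
#'
#' @param exprT1,exprT2 Genes-by-cells log-normalized matrices for the
#'   earlier and later time point.
#' @param cellsT1,cellsT2 Cell sets of the type under test (>= 3 each).
#' @param pathway Character vector of pathway genes.
#' @param alpha Raw p-value cutoff (default 0.05).
#' @return A `PathwayDECounts` list: `U`, `D`, `nTested`, `records`.
#' @export
pathway_de_counts <- function(exprT1, exprT2, cellsT1 = colnames(exprT1),
                              cellsT2 = colnames(exprT2), pathway,
                              alpha = 0.05) {
  if (length(pathway) == 0L) stop("empty pathway", call. = FALSE)
  present <- intersect(pathway, intersect(rownames(exprT1),
                                          rownames(exprT2)))
  if (length(present) < length(pathway)) {
    warning(sprintf("%d pathway gene(s) absent from matrix; skipped",
                    length(pathway) - length(present)))
  }
  if (length(present) == 0L) {
    return(structure(list(U = 0L, D = 0L, nTested = 0L,
                          records = NULL), class = "PathwayDECounts"))
  }
  # later time point is group A, so avgLogFC > 0 means up at T2
  combined <- cbind(exprT1[present, cellsT1, drop = FALSE],
                    exprT2[present, cellsT2, drop = FALSE])
  colnames(combined) <- c(paste0("t1_", cellsT1), paste0("t2_", cellsT2))
  rec <- de_two_groups(combined, paste0("t2_", cellsT2),
                       paste0("t1_", cellsT1),
                       minPct = 0, logfcThreshold = 0)
  U <- sum(rec$avgLogFC > 0 & rec$pValue < alpha)
  D <- sum(rec$avgLogFC < 0 & rec$pValue < alpha)
  structure(list(U = U, D = D, nTested = nrow(rec), records = rec),
            class = "PathwayDECounts")
}

#' Up/down regulation frequencies for one pathway
#'
#' `p(U) = U / (U + D)` and `p(D) = D / (U + D)`; pathways with no
#' significant gene (`U + D = 0`) return `NA` and are dropped from the
#' regulation-matrix normalization.
#'
#' @param counts A `PathwayDECounts` (or list with `U`, `D`).
#' @return Named numeric `c(pU =, pD =)`, or `c(NA, NA)` when degenerate.
#' @export
regulation_frequencies <- function(counts) {
  U <- counts$U
  D <- counts$D
  if (U + D == 0) return(c(pU = NA_real_, pD = NA_real_))
  c(pU = U / (U + D), pD = D / (U + D))
}

#' Pathway-by-cell-type regulation matrix
#'
#' Per cell type, the `pU` vector over pathways is normalized to sum 1,
#' the `pD` vector likewise, and the matrix entry is normalized
#' `pU - pD`: positive values (red) mark pathways whose significant genes
#' shift up at the later time point, negative values (blue) down. Entries
#' lie in `[-1, 1]` and each type's non-NA column sums to 0.
#'
#' @param freqs Named list per cell type; each element a data frame or list
#'   with `pathway`, `pU`, `pD` (NA rows = dropped pathways).
#' @return A `RegulationMatrix`: pathways x cell types numeric matrix (with
#'   NA for dropped pathways), class-attributed.
#' @export
regulation_matrix <- function(freqs) {
  pathways <- unique(unlist(lapply(freqs, function(f) f$pathway)))
  out <- matrix(NA_real_, length(pathways), length(freqs),
                dimnames = list(pathways, names(freqs)))
  for (ty in names(freqs)) {
    f <- freqs[[ty]]
    pU <- stats::setNames(f$pU, f$pathway)[pathways]
    pD <- stats::setNames(f$pD, f$pathway)[pathways]
    ok <- !is.na(pU) & !is.na(pD)
    if (!any(ok)) {
      warning("all pathways degenerate for type ", ty)
      next
    }
    out[ok, ty] <- pU[ok] / sum(pU[ok]) - pD[ok] / sum(pD[ok])
  }
  class(out) <- c("RegulationMatrix", class(out))
  out
}

#' @export
print.RegulationMatrix <- function(x, ...) {
  cat("RegulationMatrix (positive = up at the later time point):\n")
  print(round(unclass(x), 3))
  invisible(x)
}

#' Compute the regulation matrix from two labeled time points
#'
#' Convenience wrapper running [pathway_de_counts()] for every pathway and
#' cell type present at both time points, then [regulation_matrix()].
#'
#' @param exprT1,exprT2 Genes-by-cells log-normalized matrices.
#' @param labelsT1,labelsT2 Cell-type labels per time point.
#' @param pathwaySets Named list of pathway gene vectors.
#' @param alpha Raw p cutoff for the U/D counts.
#' @return A list: `matrix` (`RegulationMatrix`), `counts` (per type, per
#'   pathway `PathwayDECounts`).
#' @export
regulation_analysis <- function(exprT1, exprT2, labelsT1, labelsT2,
                                pathwaySets, alpha = 0.05) {
  types <- intersect(unique(as.character(labelsT1)),
                     unique(as.character(labelsT2)))
  counts <- lapply(types, function(ty) {
    lapply(pathwaySets, function(pw) {
      suppressWarnings(pathway_de_counts(
        exprT1, exprT2,
        colnames(exprT1)[labelsT1 == ty],
        colnames(exprT2)[labelsT2 == ty], pw, alpha))
    })
  })
  names(counts) <- types
  freqs <- lapply(counts, function(byPw) {
    fr <- t(vapply(byPw, regulation_frequencies, numeric(2)))
    data.frame(pathway = names(byPw), pU = fr[, "pU"], pD = fr[, "pD"],
               row.names = NULL)
  })
  list(matrix = regulation_matrix(freqs), counts = counts)
}

#' Cell-type-specific metabolic marker sets
#'
#' [find_all_markers()] restricted to the union of the metabolic gene sets,
#' keeping positive records with adjusted p below `adjAlpha`, plus the
#' pairwise overlap counts used for set-diagram rendering.
#'
#' @param expr Genes-by-cells log-normalized matrix.
#' @param labels Cluster label per cell.
#' @param metabolicGenes Named list of gene sets (e.g. from [read_gmt()]).
#' @param adjAlpha Adjusted-p cutoff (default 0.05).
#' @param ... Passed to [find_all_markers()].
#' @return List: `sets` (per-type marker gene vectors), `overlap`
#'   (type x type shared-gene counts), `records`.
#' @export
metabolic_markers <- function(expr, labels, metabolicGenes,
                              adjAlpha = 0.05, ...) {
  genes <- intersect(unique(unlist(metabolicGenes)), rownames(expr))
  if (length(genes) == 0L) stop("no metabolic genes in matrix",
                                call. = FALSE)
  rec <- find_all_markers(expr[genes, , drop = FALSE], labels, ...)
  rec <- rec[!is.null(rec) & rec$positive & rec$adjP < adjAlpha, ,
             drop = FALSE]
  types <- sort(unique(as.character(labels)))
  sets <- lapply(types, function(ty) rec$gene[rec$cluster == ty])
  names(sets) <- types
  overlap <- outer(types, types, Vectorize(function(a, b) {
    length(intersect(sets[[a]], sets[[b]]))
  }))
  dimnames(overlap) <- list(types, types)
  list(sets = sets, overlap = overlap, records = rec)
}

#' Disease-gene localization maps
#'
#' For each disease-gene class (e.g. hereditary deafness genes, GWAS hits),
#' the cluster-averaged z-score matrix of the class's genes; genes absent
#' from the expression matrix are listed separately.
#'
#' @param expr Genes-by-cells log-normalized matrix.
#' @param labels Cluster label per cell.
#' @param diseaseGenes Named list of gene-set vectors (one per class).
#' @return Named list per class: `zscores` (genes x clusters matrix, possibly
#'   0-row) and `absent` (genes not in the matrix).
#' @export
disease_map <- function(expr, labels, diseaseGenes) {
  lapply(diseaseGenes, function(genes) {
    present <- intersect(genes, rownames(expr))
    z <- if (length(present)) {
      celltype_zscore_matrix(expr, labels, present)
    } else {
      matrix(numeric(0), 0, length(unique(labels)))
    }
    list(zscores = z, absent = setdiff(genes, present))
  })
}
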