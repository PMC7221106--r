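#' QC thresholds
#'
#' Defaults are the published filtering bounds for this tissue: cells with
#' fewer than 200 detected genes or 1,500 UMI, or more than 3,000 detected
#' genes or 15,000 UMI, or more than 5\% mitochondrial or 5\% stress-gene
#' UMI, are excluded; genes must be detected in at least 10 cells.
#' Fractions are UMI shares, not gene-count shares.
#'
#' @param minGenes,minUMI,maxGenes,maxUMI Complexity / depth bounds.
#' @param maxMitoFrac,maxStressFrac Maximum UMI share of mito/stress genes.
#' @param minCellsPerGene Gene detection floor.
#' @param conjunctive If `TRUE`, the low (and high) complexity bounds must
#'   both be violated to exclude a cell; default is exclusion on any single
#'   bound, the common reading of the paired thresholds.
#' @return A list of class `QCThresholds`.
#' @export
qc_thresholds <- function(minGenes = 200L, minUMI = 1500L, maxGenes = 3000L,
                          maxUMI = 15000L, maxMitoFrac = 0.05,
                          maxStressFrac = 0.05, minCellsPerGene = 10L,
                          conjunctive = FALSE) {
  stopifnot(minGenes < maxGenes, minUMI < maxUMI,
            maxMitoFrac > 0, maxMitoFrac < 1,
            maxStressFrac > 0, maxStressFrac < 1,
            minGenes >= 0, minUMI >= 0, minCellsPerGene >= 0)
  structure(list(minGenes = minGenes, minUMI = minUMI, maxGenes = maxGenes,
                 maxUMI = maxUMI, maxMitoFrac = maxMitoFrac,
                 maxStressFrac = maxStressFrac,
                 minCellsPerGene = minCellsPerGene,
                 conjunctive = conjunctive),
            class = "QCThresholds")
}

#' Filter genes by detection
#'
#' Keeps genes detected (count > 0) in at least `minCells` cells, preserving
#' order.
#'
#' @param counts Genes-by-cells count matrix (sparse or dense).
#' @param minCells Detection floor (default 10).
#' @return The row-subset count matrix.
#' @export
filter_genes <- function(counts, minCells = 10L) {
  stopifnot(minCells >= 0)
  detected <- Matrix::rowSums(counts > 0)
  counts[detected >= minCells, , drop = FALSE]
}

#' Cell-level QC report
#'
#' Computes per-cell detected genes, total UMI, and mito/stress UMI shares,
#' and flags each violated rule. A cell is retained iff its violation list
#' is empty.
#'
#' @param counts Genes-by-cells count matrix.
#' @param thresholds A [qc_thresholds()].
#' @param mitoGenes,stressGenes Character vectors of gene names; default to
#'   the `mt-` / `stress-` naming convention.
#' @return A `QCReport`: data frame `cells` (cell, detectedGenes, totalUMI,
#'   mitoFrac, stressFrac, retained, violations), plus `nBefore`, `nAfter`.
#' @export
filter_cells <- function(counts, thresholds = qc_thresholds(),
                         mitoGenes = grep("^mt-", rownames(counts),
                                          value = TRUE),
                         stressGenes = grep("^stress-", rownames(counts),
                                            value = TRUE)) {
  th <- thresholds
  if (ncol(counts) == 0L) {
    rep0 <- list(cells = data.frame(cell = character(0)),
                 nBefore = 0L, nAfter = 0L, thresholds = th)
    class(rep0) <- "QCReport"
    return(rep0)
  }
  stopifnot(all(mitoGenes %in% rownames(counts)),
            all(stressGenes %in% rownames(counts)))
  detected <- Matrix::colSums(counts > 0)
  total <- Matrix::colSums(counts)
  mitoUMI <- if (length(mitoGenes))
    Matrix::colSums(counts[mitoGenes, , drop = FALSE]) else 0
  stressUMI <- if (length(stressGenes))
    Matrix::colSums(counts[stressGenes, , drop = FALSE]) else 0
  mitoFrac <- ifelse(total > 0, mitoUMI / total, 0)
  stressFrac <- ifelse(total > 0, stressUMI / total, 0)
  lowG <- detected < th$minGenes
  lowU <- total < th$minUMI
  highG <- detected > th$maxGenes
  highU <- total > th$maxUMI
  if (th$conjunctive) {
    lowG <- lowU <- lowG & lowU
    highG <- highU <- highG & highU
  }
  flags <- cbind(low_genes = lowG, low_umi = lowU, high_genes = highG,
                 high_umi = highU, high_mito = mitoFrac > th$maxMitoFrac,
                 high_stress = stressFrac > th$maxStressFrac)
  violations <- apply(flags, 1L, function(f) colnames(flags)[f],
                      simplify = FALSE)
  retained <- rowSums(flags) == 0
  cells <- data.frame(cell = colnames(counts), detectedGenes = detected,
                      totalUMI = total, mitoFrac = mitoFrac,
                      stressFrac = stressFrac, retained = retained,
                      row.names = NULL)
  cells$violations <- I(unname(violations))
  rep <- list(cells = cells, nBefore = ncol(counts),
              nAfter = sum(retained), thresholds = th)
  class(rep) <- "QCReport"
  rep
}

#' @export
print.QCReport <- function(x, ...) {
  cat(sprintf("QCReport: %d of %d cells retained\n", x$nAfter, x$nBefore))
  if (x$nBefore > x$nAfter) {
    tab <- table(unlist(x$cells$violations))
    for (nm in names(tab)) cat(sprintf("  %s: %d\n", nm, tab[[nm]]))
  }
  invisible(x)
}

#' Retained cells of a QC report
#' @param counts The matrix the report was computed on.
#' @param report A `QCReport`.
#' @return The column-subset matrix of retained cells.
#' @export
retained_cells <- function(counts, report) {
  counts[, report$cells$retained, drop = FALSE]
}

#' Depth-normalize and log-transform
#'
#' `log(1 + scaleFactor * count / cellTotal)`; column sums of the
#' pre-log normalized values all equal `scaleFactor`.
#'
#' @param counts Genes-by-cells count matrix; no all-zero cells.
#' @param scaleFactor Target depth (default 10,000).
#' @return Dense genes-by-cells matrix of nonnegative reals.
#' @export
normalize_log <- function(counts, scaleFactor = 1e4) {
  total <- Matrix::colSums(counts)
  if (any(total == 0)) {
    stop("cell(s) with zero total counts: ",
         paste(utils::head(colnames(counts)[total == 0]), collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(counts)
  log1p(sweep(m, 2L, scaleFactor / total, `*`))
}

#' Select highly variable genes
#'
#' Ranks genes by the residual of a loess fit of log dispersion
#' (variance/mean of the depth-normalized counts) on log mean, and keeps
#' the top `n`. Genes whose variability exceeds the mean-dispersion trend
#' carry the biological structure; restricting the scaled matrix to them
#' keeps the planted programs above the noise floor of the PCA.
#'
#' @param expr Genes-by-cells log-normalized matrix.
#' @param n Number of genes to keep (default 500).
#' @param span Loess span for the mean-dispersion trend.
#' @return Character vector of selected gene names (length <= `n`).
#' @export
select_variable_genes <- function(expr, n = 500L, span = 0.3) {
  cnt <- expm1(as.matrix(expr))
  mu <- rowMeans(cnt)
  v <- apply(cnt, 1L, stats::var)
  ok <- mu > 0 & v > 0
  if (sum(ok) <= n) return(rownames(expr)[ok])
  lmu <- log(mu[ok])
  ldisp <- log(v[ok] / mu[ok])
  fit <- stats::loess(ldisp ~ lmu, span = span)
  resid <- ldisp - stats::predict(fit, lmu)
  names(sort(stats::setNames(resid, rownames(expr)[ok]),
             decreasing = TRUE))[seq_len(n)]
}

#' Regress out covariates and scale genes
#'
#' Per gene: residual of an ordinary least-squares fit on the covariates
#' (typically total UMI, mito fraction, stress fraction), then centered,
#' scaled to unit variance and clipped. Genes with zero residual variance
#' become all-zero rows.
#'
#' @param expr Genes-by-cells log-normalized matrix.
#' @param covariates Cells-by-k numeric matrix or data frame (may be NULL
#'   for plain z-scoring).
#' @param clip Symmetric clipping bound on the scaled values (default 10).
#' @return Dense genes-by-cells scaled matrix.
#' @export
regress_and_scale <- function(expr, covariates = NULL, clip = 10) {
  n <- ncol(expr)
  if (is.null(covariates)) {
    X <- matrix(1, n, 1L)
  } else {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == n)
    X <- cbind(Intercept = 1, covariates)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      drop <- setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])
      warning("dropping collinear covariate column(s): ",
              paste(colnames(X)[drop], collapse = ", "))
      X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    }
  }
  # one QR for all genes: residuals of t(expr) ~ X
  res <- qr.resid(qr(X), t(as.matrix(expr)))
  res <- t(res)                         # genes x cells
  mu <- rowMeans(res)
  res <- res - mu
  sdev <- sqrt(rowSums(res^2) / (n - 1L))
  zero <- sdev < 1e-12
  sdev[zero] <- 1
  out <- res / sdev
  out[zero, ] <- 0
  out[out > clip] <- clip
  out[out < -clip] <- -clip
  out
}
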