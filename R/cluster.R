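#' Principal-component embedding
#'
#' PCA of the scaled genes-by-cells matrix, computed from the eigen
#' decomposition of the smaller Gram matrix. Deterministic up to component
#' sign; the sign is fixed so the largest-magnitude gene loading of each
#' component is positive.
#'
#' @param scaled Genes-by-cells scaled matrix (from [regress_and_scale()]).
#' @param nComponents Number of components (>= 2).
#' @return An `Embedding`: `coords` (cells x components), and
#'   `explainedVariance` (fraction per component).
#' @export
reduce_dims <- function(scaled, nComponents = 20L) {
  stopifnot(nComponents >= 2)
  X <- t(as.matrix(scaled))              # cells x genes
  X <- scale(X, center = TRUE, scale = FALSE)
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p) {
    e <- eigen(tcrossprod(X), symmetric = TRUE)
    vals <- pmax(e$values, 0)
    tol <- max(vals) * 1e-9
    rank <- sum(vals > tol)
    k <- nComponents
    if (k > rank) {
      warning(sprintf("nComponents (%d) exceeds rank (%d); truncating",
                      k, rank))
      k <- rank
    }
    d <- sqrt(vals[seq_len(k)])
    U <- e$vectors[, seq_len(k), drop = FALSE]
    scores <- U * rep(d, each = n)
    loadings <- crossprod(X, U) / rep(d, each = p)
  } else {
    s <- svd(X, nu = min(n, p), nv = min(n, p))
    tol <- max(s$d) * 1e-9
    rank <- sum(s$d > tol)
    k <- nComponents
    if (k > rank) {
      warning(sprintf("nComponents (%d) exceeds rank (%d); truncating",
                      k, rank))
      k <- rank
    }
    vals <- s$d^2
    d <- s$d[seq_len(k)]
    scores <- s$u[, seq_len(k), drop = FALSE] * rep(d, each = n)
    loadings <- s$v[, seq_len(k), drop = FALSE]
  }
  for (j in seq_len(ncol(scores))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) scores[, j] <- -scores[, j]
  }
  rownames(scores) <- colnames(scaled)
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  structure(list(coords = scores,
                 explainedVariance = vals[seq_len(ncol(scores))] / sum(vals)),
            class = "Embedding")
}

# shared-nearest-neighbor graph with Jaccard weights, pruned below `prune`
.snn_graph <- function(coords, kNeighbors = 20L, prune = 1 / 15) {
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  k <- min(kNeighbors, n - 1L)
  nn <- t(apply(d, 1L, function(r) order(r)[seq_len(k + 1L)]))  # incl. self
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k + 1L),
                            j = as.integer(t(nn)), x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(A)
  jac <- shared
  jac@x <- jac@x / (2 * (k + 1L) - jac@x)
  jac@x[jac@x < prune] <- 0
  jac <- Matrix::drop0(jac)
  Matrix::diag(jac) <- 0
  igraph::graph_from_adjacency_matrix(Matrix::drop0(jac), mode = "undirected",
                                      weighted = TRUE)
}

#' Cluster cells at one resolution
#'
#' Builds a shared-nearest-neighbor graph on the embedding and runs
#' modularity (Louvain) community detection at the given resolution.
#' Cluster ids are relabeled by decreasing size.
#'
#' @param emb An [reduce_dims()] `Embedding` (or a plain cells x dims matrix).
#' @param resolution Modularity resolution parameter.
#' @param kNeighbors Neighborhood size for the SNN graph.
#' @param seed Integer seed for the community detection.
#' @param snn Optional precomputed SNN graph (reused across a scan).
#' @return A `ClusteringResult`: `labels` (named integer per cell),
#'   `resolution`, `nClusters`, `oobError` (NA until scored).
#' @export
cluster_at_resolution <- function(emb, resolution, kNeighbors = 20L,
                                  seed = 1L, snn = NULL) {
  coords <- if (inherits(emb, "Embedding")) emb$coords else as.matrix(emb)
  if (nrow(coords) < 3L) stop("need at least 3 cells", call. = FALSE)
  stopifnot(kNeighbors < nrow(coords))
  if (is.null(snn)) snn <- .snn_graph(coords, kNeighbors)
  set.seed(seed)
  comm <- igraph::cluster_louvain(snn, resolution = resolution)
  memb <- igraph::membership(comm)
  sizes <- table(memb)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  relabel <- stats::setNames(seq_along(ord), names(sizes)[ord])
  labels <- as.integer(relabel[as.character(memb)])
  names(labels) <- rownames(coords)
  structure(list(labels = labels, resolution = resolution,
                 nClusters = length(sizes), oobError = NA_real_),
            class = "ClusteringResult")
}

#' @export
print.ClusteringResult <- function(x, ...) {
  cat(sprintf("ClusteringResult: %d clusters at resolution %.2f (OOB %s)\n",
              x$nClusters, x$resolution,
              ifelse(is.na(x$oobError), "unscored",
                     sprintf("%.3f", x$oobError))))
  invisible(x)
}

#' Out-of-bag error of a clustering
#'
#' Misclassification rate of a bagged decision-tree ensemble (random forest)
#' predicting the cluster labels from the embedding coordinates, estimated
#' on the out-of-bag samples. Used as a cluster-quality score: overclustered
#' partitions split homogeneous groups and drive the OOB error up.
#'
#' @param emb `Embedding` or cells x dims matrix.
#' @param labels Cluster label per cell.
#' @param nTrees Trees in the ensemble.
#' @param seed Integer seed.
#' @return OOB misclassification rate in `[0, 1]`.
#' @export
oob_error <- function(emb, labels, nTrees = 100L, seed = 1L) {
  coords <- if (inherits(emb, "Embedding")) emb$coords else as.matrix(emb)
  y <- factor(labels)
  if (nlevels(y) < 2L) {
    warning("single cluster: OOB error defined as 0")
    return(0)
  }
  set.seed(seed)
  rf <- randomForest::randomForest(x = coords, y = y, ntree = nTrees)
  unname(rf$err.rate[nTrees, "OOB"])
}

#' Scan a resolution grid and select by the OOB rule
#'
#' Clusters at every grid resolution, scores each partition by OOB error,
#' and selects, among partitions whose OOB error is within
#' `selectionTolerance` of the minimum, the one with the largest cluster
#' count (ties broken by the lowest resolution). This is the "low OOB error
#' and high cluster number" rule made explicit.
#'
#' @param emb An `Embedding`.
#' @param grid Strictly increasing resolutions; default 0.2-2.4 in 0.2 steps.
#' @param selectionTolerance OOB band above the minimum (default 0.05).
#' @param kNeighbors,nTrees,seed Passed to the clustering and OOB scoring.
#' @return A `ResolutionScan`: `selected` (a `ClusteringResult`), `all`
#'   (list of results), `table` (resolution, nClusters, oobError).
#' @export
scan_resolutions <- function(emb, grid = seq(0.2, 2.4, by = 0.2),
                             selectionTolerance = 0.05, kNeighbors = 20L,
                             nTrees = 100L, seed = 1L) {
  stopifnot(length(grid) >= 1L, !is.unsorted(grid, strictly = TRUE))
  coords <- if (inherits(emb, "Embedding")) emb$coords else as.matrix(emb)
  snn <- .snn_graph(coords, min(kNeighbors, nrow(coords) - 1L))
  results <- lapply(grid, function(r) {
    res <- cluster_at_resolution(emb, r, kNeighbors, seed = seed, snn = snn)
    res$oobError <- if (res$nClusters < 2L) 0 else
      oob_error(emb, res$labels, nTrees, seed = seed)
    res
  })
  tab <- data.frame(resolution = grid,
                    nClusters = vapply(results, `[[`, 1L, "nClusters"),
                    oobError = vapply(results, `[[`, 1, "oobError"))
  if (any(diff(tab$nClusters) < 0)) {
    message("[scan] cluster count is not monotone in resolution")
  }
  best <- .select_scan(tab, selectionTolerance)
  structure(list(selected = results[[best]], all = results, table = tab,
                 selectionTolerance = selectionTolerance),
            class = "ResolutionScan")
}

# tolerance-band-then-max-k rule: among rows with oobError within
# `tolerance` of the minimum, pick max nClusters; ties -> lowest resolution
.select_scan <- function(tab, tolerance) {
  cand <- which(tab$oobError <= min(tab$oobError) + tolerance)
  cand[order(-tab$nClusters[cand], tab$resolution[cand])][1L]
}

#' @export
print.ResolutionScan <- function(x, ...) {
  cat("ResolutionScan:\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("selected: resolution %.2f with %d clusters (OOB %.3f)\n",
              x$selected$resolution, x$selected$nClusters,
              x$selected$oobError))
  invisible(x)
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same cells;
#' 1 for identical partitions, ~0 for independent ones.
#'
#' @param a,b Label vectors of equal length.
#' @return The ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sumIJ <- sum(comb2(tab))
  sumI <- sum(comb2(rowSums(tab)))
  sumJ <- sum(comb2(colSums(tab)))
  n <- comb2(length(a))
  expected <- sumI * sumJ / n
  maxIdx <- (sumI + sumJ) / 2
  if (maxIdx == expected) return(1)
  (sumIJ - expected) / (maxIdx - expected)
}
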