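#' Order cells along a pseudotime axis
#'
#' Builds a minimum spanning tree over cluster centroids in the embedding,
#' projects every cell onto its nearest tree edge, and takes pseudotime as
#' the arc length from the root cluster's centroid, normalized to `[0, 1]`.
#' A single degree-3 centroid is permitted and yields two branches; trees
#' with more than one bifurcation are rejected.
#'
#' For unbranched trees the initial MST pseudotime is refined by a
#' principal-curve pass: each embedding coordinate is smoothed against the
#' current pseudotime (lowess) and cells are re-projected onto the fitted
#' curve, which removes the quantization of the piecewise-linear
#' centroid path.
#'
#' @param emb `Embedding` or cells x dims matrix.
#' @param labels Cluster label per cell.
#' @param rootCluster Cluster whose centroid anchors pseudotime 0.
#' @param refine Apply the principal-curve refinement (unbranched trees
#'   only; default TRUE).
#' @param refineIters,refineSpan Iterations and lowess span of the
#'   refinement.
#' @return A `Trajectory`: `pseudotime` (named, in `[0, 1]`), `branch`
#'   (per cell; `"trunk"` before the bifurcation), `rootCluster`,
#'   `centroids`, `edges`.
#' @export
order_cells <- function(emb, labels, rootCluster, refine = TRUE,
                        refineIters = 4L, refineSpan = 0.2) {
  coords <- if (inherits(emb, "Embedding")) emb$coords else as.matrix(emb)
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(coords))
  if (!rootCluster %in% labels) {
    stop("rootCluster not present: ", rootCluster, call. = FALSE)
  }
  lev <- sort(unique(labels))
  if (length(lev) < 2L) {
    stop("need at least 2 clusters to build a trajectory tree", call. = FALSE)
  }
  centroids <- t(vapply(lev, function(cl) {
    colMeans(coords[labels == cl, , drop = FALSE])
  }, numeric(ncol(coords))))
  build_tree <- function(cent) {
    D <- as.matrix(stats::dist(cent))
    igraph::mst(igraph::graph_from_adjacency_matrix(
      D, mode = "undirected", weighted = TRUE))
  }
  # prune spurs: a single leaf centroid hanging directly off a branch node
  # is overclustering noise on the manifold, not a biological branch
  keep <- seq_along(lev)
  repeat {
    tree <- build_tree(centroids[keep, , drop = FALSE])
    deg <- igraph::degree(tree)
    hubs <- which(deg >= 3L)
    rootPos <- match(as.character(rootCluster), lev[keep])
    spurs <- integer(0)
    for (h in hubs) {
      nb <- as.integer(igraph::neighbors(tree, h))
      leafNb <- nb[deg[nb] == 1L & nb != rootPos]
      spurs <- c(spurs, leafNb)
    }
    if (length(spurs) == 0L || length(keep) <= 2L) break
    # drop the spur closest to its hub, one at a time
    d2hub <- vapply(spurs, function(s) {
      e <- igraph::incident(tree, s)
      igraph::edge_attr(tree, "weight", e)[1L]
    }, numeric(1))
    keep <- keep[-spurs[which.min(d2hub)]]
  }
  centroids <- centroids[keep, , drop = FALSE]
  lev <- lev[keep]
  tree <- build_tree(centroids)
  deg <- igraph::degree(tree)
  branchNodes <- which(deg >= 3L)
  if (length(branchNodes) > 1L) {
    stop("embedding yields more than one bifurcation; trajectory undefined",
         call. = FALSE)
  }
  root <- match(as.character(rootCluster), lev)
  dRoot <- igraph::distances(tree, v = root)[1L, ]
  el <- igraph::as_edgelist(tree, names = FALSE)
  # orient each edge parent -> child (parent closer to the root)
  swap <- dRoot[el[, 1L]] > dRoot[el[, 2L]]
  el[swap, ] <- el[swap, c(2L, 1L)]
  n <- nrow(coords)
  bestD2 <- rep(Inf, n)
  arc <- numeric(n)
  edgeOf <- integer(n)
  for (e in seq_len(nrow(el))) {
    u <- el[e, 1L]; v <- el[e, 2L]
    a <- centroids[u, ]; b <- centroids[v, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- as.numeric((coords %*% ab) - sum(a * ab)) / len2
    t <- pmin(pmax(t, 0), 1)
    proj <- outer(t, ab)
    diff <- coords - rep(a, each = n) - proj
    d2 <- rowSums(diff^2)
    upd <- d2 < bestD2
    bestD2[upd] <- d2[upd]
    arc[upd] <- dRoot[u] + t[upd] * sqrt(len2)
    edgeOf[upd] <- e
  }
  pt <- if (max(arc) > 0) arc / max(arc) else arc
  if (refine && length(branchNodes) == 0L) {
    # coarse-to-fine span schedule avoids end-folding of the fitted curve
    for (f in seq(0.5, refineSpan, length.out = refineIters)) {
      pt <- .principal_curve_pt(coords, pt, iters = 1L, span = f)
    }
    # re-anchor orientation at the root cluster
    if (mean(pt[labels == rootCluster]) > stats::median(pt)) pt <- 1 - pt
  }
  names(pt) <- rownames(coords)
  branch <- rep("branch1", n)
  if (length(branchNodes) == 1L) {
    b <- branchNodes[1L]
    cut <- igraph::delete_vertices(tree, b)
    comp <- igraph::components(cut)$membership
    full <- rep(NA_integer_, length(lev))
    full[-b] <- comp
    limbOfEdge <- ifelse(el[, 1L] == b, full[el[, 2L]], full[el[, 1L]])
    rootLimb <- full[root]
    if (is.na(rootLimb)) rootLimb <- -1L   # root is the bifurcation itself
    others <- sort(unique(limbOfEdge[limbOfEdge != rootLimb]))
    lab <- stats::setNames(paste0("branch", seq_along(others)), others)
    cellLimb <- limbOfEdge[edgeOf]
    branch <- ifelse(cellLimb == rootLimb, "trunk",
                     lab[as.character(cellLimb)])
  }
  names(branch) <- rownames(coords)
  structure(list(pseudotime = pt, branch = branch,
                 rootCluster = rootCluster, centroids = centroids,
                 edges = el, clusterLevels = lev),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf(
    "Trajectory: %d cells, root cluster %s, %d branch label(s)\n",
    length(x$pseudotime), x$rootCluster, length(unique(x$branch))))
  invisible(x)
}

#' Number of post-bifurcation branches
#' @param trajectory A `Trajectory`.
#' @return Count of distinct branch labels other than `"trunk"`.
#' @export
n_branches <- function(trajectory) {
  length(setdiff(unique(trajectory$branch), "trunk"))
}

# one principal-curve iteration: smooth each coordinate against pseudotime,
# then project every cell onto the fitted polyline and take its arc length
.principal_curve_pt <- function(coords, pt, iters = 4L, span = 0.2,
                                gridN = 100L) {
  n <- nrow(coords)
  for (it in seq_len(iters)) {
    grid <- seq(min(pt), max(pt), length.out = gridN)
    curve <- vapply(seq_len(ncol(coords)), function(j) {
      stats::approx(stats::lowess(pt, coords[, j], f = span),
                    xout = grid, rule = 2, ties = mean)$y
    }, numeric(gridN))
    seglen <- sqrt(rowSums((curve[-1L, , drop = FALSE] -
                            curve[-gridN, , drop = FALSE])^2))
    cum <- c(0, cumsum(seglen))
    best <- rep(Inf, n)
    arc <- numeric(n)
    for (e in seq_len(gridN - 1L)) {
      a <- curve[e, ]
      ab <- curve[e + 1L, ] - a
      l2 <- sum(ab^2)
      if (l2 < 1e-24) next
      t <- pmin(pmax(as.numeric((coords %*% ab) - sum(a * ab)) / l2, 0), 1)
      d2 <- rowSums((coords - rep(a, each = n) - outer(t, ab))^2)
      upd <- d2 < best
      best[upd] <- d2[upd]
      arc[upd] <- cum[e] + t[upd] * seglen[e]
    }
    pt <- if (max(arc) > 0) arc / max(arc) else arc
  }
  pt
}

# natural cubic spline basis with 3 internal knots at pseudotime quantiles,
# nudged inside the boundary when cells pile up at the ends
.pt_basis <- function(pt) {
  rng <- range(pt)
  eps <- diff(rng) * 1e-3
  knots <- stats::quantile(pt, c(0.25, 0.5, 0.75), names = FALSE)
  knots <- pmin(pmax(knots, rng[1] + eps), rng[2] - eps)
  knots <- unique(knots)
  splines::ns(pt, knots = knots, Boundary.knots = rng)
}

#' Differential expression along pseudotime
#'
#' Per gene, compares a natural cubic spline fit of log-normalized
#' expression on pseudotime (3 internal knots at quantiles) against an
#' intercept-only model by an F test, then controls the false discovery
#' rate by Benjamini-Hochberg.
#'
#' @param expr Genes-by-cells log-normalized matrix.
#' @param trajectory A [order_cells()] result (or numeric pseudotime).
#' @param fdr FDR cutoff (default 0.1).
#' @param returnAll Return all genes (with a `significant` flag) instead of
#'   only the significant ones.
#' @return Data frame: gene, pValue, qValue (and `significant` when
#'   `returnAll = TRUE`), ordered by qValue.
#' @export
de_along_pseudotime <- function(expr, trajectory, fdr = 0.1,
                                returnAll = FALSE) {
  pt <- if (inherits(trajectory, "Trajectory")) trajectory$pseudotime
        else as.numeric(trajectory)
  if (length(pt) < 50L) stop("need at least 50 cells", call. = FALSE)
  if (stats::sd(pt) < 1e-12) stop("pseudotime is constant", call. = FALSE)
  X <- cbind(1, .pt_basis(pt))
  Y <- t(as.matrix(expr))
  n <- nrow(Y)
  qrX <- qr(X)
  rss1 <- colSums(qr.resid(qrX, Y)^2)
  rss0 <- colSums(sweep(Y, 2L, colMeans(Y))^2)
  df1 <- ncol(X) - 1L
  df2 <- n - ncol(X)
  Fstat <- ((rss0 - rss1) / df1) / (rss1 / df2)
  p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  p[rss0 < 1e-12 | rss1 < 1e-12] <- 1   # flat or perfectly fitted genes
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(gene = rownames(expr), pValue = p, qValue = q,
                    row.names = NULL)
  out <- out[order(out$qValue, out$pValue, out$gene), , drop = FALSE]
  if (returnAll) {
    out$significant <- out$qValue <= fdr
    out
  } else {
    out[out$qValue <= fdr, , drop = FALSE]
  }
}

#' Cluster significant genes into phase modules
#'
#' Each gene's z-scored expression is smoothed against pseudotime with the
#' same spline basis used for testing and evaluated on a fixed grid; the
#' resulting trend curves (in per-gene SD units) are partitioned by seeded
#' k-means on their shapes (unit-scaled curves). A distinct expression
#' trend must have amplitude: only genes whose smoothed curve spans at
#' least `minAmplitude` SDs drive the clustering and the `k = "auto"`
#' selection (k in 2..8 by mean silhouette width); the remaining
#' significant genes (near-flat false discoveries of the FDR screen) are
#' then assigned to the nearest module centroid, so every significant gene
#' carries exactly one module id. Modules are relabeled in order of their
#' peak position, so `module1` peaks earliest.
#'
#' @param expr Genes-by-cells log-normalized matrix.
#' @param trajectory A `Trajectory` (or numeric pseudotime).
#' @param sigGenes Genes to cluster (e.g. from [de_along_pseudotime()]).
#' @param k Number of modules, or `"auto"`.
#' @param gridPoints Grid resolution for the smoothed trends (default 50).
#' @param minAmplitude Trend-range floor, in per-gene SDs (default 1).
#' @param seed Integer seed for k-means.
#' @return A `PhaseModules`: `modules` (named gene -> module id), `trends`
#'   (grid x genes, per-gene SD units), `grid`, `k`, `silhouette` (when
#'   auto), `trendGenes` (the amplitude-qualifying genes).
#' @export
cluster_gene_trends <- function(expr, trajectory, sigGenes, k = "auto",
                                gridPoints = 50L, minAmplitude = 1,
                                seed = 1L) {
  pt <- if (inherits(trajectory, "Trajectory")) trajectory$pseudotime
        else as.numeric(trajectory)
  sigGenes <- intersect(sigGenes, rownames(expr))
  if (!identical(k, "auto") && length(sigGenes) < k) {
    stop("fewer significant genes than modules requested", call. = FALSE)
  }
  B <- .pt_basis(pt)
  X <- cbind(1, B)
  Z <- t(scale(t(as.matrix(expr[sigGenes, , drop = FALSE]))))
  Z[is.na(Z)] <- 0                       # zero-variance genes
  coefs <- qr.coef(qr(X), t(Z))
  grid <- seq(0, 1, length.out = gridPoints)
  Xg <- cbind(1, stats::predict(B, grid))
  M <- t(Xg %*% coefs)                   # genes x grid, SD units
  rownames(M) <- sigGenes
  amp <- apply(M, 1L, function(x) diff(range(x)))
  strong <- amp >= minAmplitude
  if (sum(strong) < 2L) strong <- amp >= stats::median(amp)  # degenerate
  shape <- function(m) {
    s <- t(scale(t(m)))
    s[is.na(s)] <- 0
    s
  }
  Ms <- shape(M[strong, , drop = FALSE])
  kmSeeded <- function(kk) {
    set.seed(seed)
    stats::kmeans(Ms, centers = kk, nstart = 10L, iter.max = 50L)
  }
  sil <- NULL
  if (identical(k, "auto")) {
    kCand <- 2:min(8L, nrow(Ms) - 1L)
    d <- stats::dist(Ms)
    sil <- vapply(kCand, function(kk) {
      cl <- kmSeeded(kk)$cluster
      mean(cluster::silhouette(cl, d)[, "sil_width"])
    }, numeric(1))
    k <- kCand[which.max(sil)]
    sil <- stats::setNames(sil, kCand)
  }
  if (nrow(Ms) < k) stop("fewer trend genes than modules requested",
                         call. = FALSE)
  km <- kmSeeded(k)
  assign <- integer(length(sigGenes))
  names(assign) <- sigGenes
  assign[rownames(Ms)] <- km$cluster
  weak <- setdiff(sigGenes, rownames(Ms))
  if (length(weak)) {
    Mw <- shape(M[weak, , drop = FALSE])
    d2c <- apply(Mw, 1L, function(x) {
      which.min(colSums((t(km$centers) - x)^2))
    })
    assign[weak] <- d2c
  }
  peak <- vapply(seq_len(k), function(j) {
    grid[which.max(colMeans(M[names(assign)[assign == j], , drop = FALSE]))]
  }, numeric(1))
  relabel <- stats::setNames(order(order(peak, seq_len(k))), seq_len(k))
  modules <- stats::setNames(sprintf("module%d", relabel[assign]), sigGenes)
  structure(list(modules = modules, trends = t(M), grid = grid, k = k,
                 silhouette = sil, trendGenes = rownames(Ms)),
            class = "PhaseModules")
}

#' @export
print.PhaseModules <- function(x, ...) {
  cat(sprintf("PhaseModules: %d genes in %d modules\n",
              length(x$modules), x$k))
  print(table(x$modules))
  invisible(x)
}

#' Pick a root cluster by progenitor-marker expression
#'
#' The cluster with the highest mean expression of a progenitor marker set
#' (the Sox2-style anchoring of trajectory orientation).
#'
#' @param expr Genes-by-cells log-normalized matrix.
#' @param labels Cluster label per cell.
#' @param progenitorMarkers Character vector of marker genes.
#' @return The root cluster label.
#' @export
pick_root_cluster <- function(expr, labels, progenitorMarkers) {
  genes <- intersect(progenitorMarkers, rownames(expr))
  if (length(genes) == 0L) stop("no progenitor markers in matrix",
                                call. = FALSE)
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  score <- vapply(lev, function(cl) {
    mean(expr[genes, labels == cl, drop = FALSE])
  }, numeric(1))
  lev[which.max(score)]
}
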