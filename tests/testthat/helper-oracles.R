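# Shared fixtures and independent oracles used across test files.

# Gaussian blob coordinates: k centers sep apart on a simplex-ish layout
make_blobs <- function(n_per, k, d = 5, sep = 6, sd = 1, seed = 1) {
  set.seed(seed)
  centers <- matrix(0, k, d)
  for (j in seq_len(k)) centers[j, ((j - 1) %% d) + 1] <- sep * ceiling(j / d)
  coords <- do.call(rbind, lapply(seq_len(k), function(j) {
    sweep(matrix(rnorm(n_per * d, sd = sd), n_per, d), 2, centers[j, ], `+`)
  }))
  rownames(coords) <- sprintf("cell%04d", seq_len(nrow(coords)))
  list(coords = coords, labels = rep(seq_len(k), each = n_per))
}

# leave-one-out nearest-centroid misclassification rate
loo_nearest_centroid_error <- function(coords, labels) {
  labels <- as.character(labels)
  lev <- unique(labels)
  n <- nrow(coords)
  wrong <- 0L
  sums <- rowsum(coords, labels)
  cnts <- table(labels)[rownames(sums)]
  for (i in seq_len(n)) {
    cent <- sums
    cent[labels[i], ] <- cent[labels[i], ] - coords[i, ]
    sizes <- as.numeric(cnts)
    sizes[rownames(sums) == labels[i]] <-
      sizes[rownames(sums) == labels[i]] - 1
    cent <- cent / sizes
    d2 <- rowSums(sweep(cent, 2, coords[i, ])^2)
    if (rownames(sums)[which.min(d2)] != labels[i]) wrong <- wrong + 1L
  }
  wrong / n
}

# brute-force recovery-curve AUC for a single expression vector
ras_bruteforce <- function(exprVec, geneNames, targets, topFraction) {
  nGenes <- length(exprVec)
  maxRank <- ceiling(topFraction * nGenes)
  ranking <- geneNames[order(-exprVec, geneNames)]
  hits <- cumsum(ranking %in% targets)[seq_len(maxRank)]
  auc <- sum(hits)
  nT <- length(targets)
  maxAuc <- sum(pmin(seq_len(maxRank), nT))
  auc / maxAuc
}

# direct-summation Jensen-Shannon divergence (log base 2)
jsd_direct <- function(p, q) {
  m <- (p + q) / 2
  s <- 0
  for (i in seq_along(p)) {
    if (p[i] > 0) s <- s + 0.5 * p[i] * log2(p[i] / m[i])
    if (q[i] > 0) s <- s + 0.5 * q[i] * log2(q[i] / m[i])
  }
  s
}

# small generator configuration for fast unit tests
small_config <- function(...) {
  args <- list(nGenes = 300L, nTypes = 3L, cellsPerType = 60L,
               markersPerType = 8L, markerFold = 6, baseMean = 1.5,
               mitoGeneCount = 5L, stressGeneCount = 5L)
  do.call(generator_config, utils::modifyList(args, list(...)))
}

# counts fixture with one cell engineered per QC rule boundary
qc_boundary_counts <- function(nGenes = 3100L) {
  # columns: exactly-200 genes, 199 genes, UMI exactly 1500, UMI 1499,
  # 3001 genes, UMI 15001, mito exactly 5%, mito just above 5%
  m <- matrix(0L, nGenes, 8)
  rownames(m) <- c(sprintf("g%04d", seq_len(nGenes - 2L)), "mt-1", "stress-1")
  colnames(m) <- sprintf("cell%d", 1:8)
  m[1:200, 1] <- 10L                       # 200 genes, 2000 UMI
  m[1:199, 2] <- 10L                       # 199 genes -> low_genes
  m[1:300, 3] <- 5L                        # 300 genes, 1500 UMI
  m[1:300, 4] <- 5L; m[300, 4] <- 4L       # 1499 UMI -> low_umi
  m[1:3001, 5] <- 2L                       # 3001 genes -> high_genes
  m[1:300, 6] <- 50L; m[300, 6] <- 51L     # 15001 UMI -> high_umi
  m[1:285, 7] <- 10L; m["mt-1", 7] <- 150L # mito exactly 5% of 3000
  m[1:285, 8] <- 10L; m["mt-1", 8] <- 151L # just above 5%
  m
}
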