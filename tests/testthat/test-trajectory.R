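# coordinates along a noisy 1-D gradient, segment labels for the tree
gradient_fixture <- function(n = 300, d = 5, noise = 0.3, seed = 1) {
  set.seed(seed)
  t <- runif(n)
  coords <- cbind(10 * t, 3 * sin(2 * t)) %*% matrix(rnorm(2 * d), 2, d) +
    matrix(rnorm(n * d, sd = noise), n, d)
  rownames(coords) <- sprintf("c%04d", seq_len(n))
  list(coords = coords, t = t,
       labels = as.integer(cut(t, breaks = 5)))
}

test_that("pseudotime tracks a noisy 1-D gradient and is anchored at the root", {
  fx <- gradient_fixture()
  rootCluster <- fx$labels[which.min(fx$t)]
  tr <- order_cells(fx$coords, fx$labels, rootCluster)
  rho <- cor(tr$pseudotime, fx$t, method = "spearman")
  expect_gte(abs(rho), 0.95)
  expect_gt(rho, 0)   # orientation fixed by the root
  expect_lt(mean(tr$pseudotime[fx$labels == rootCluster]), 0.1)
})

test_that("pseudotime is invariant under cell permutation", {
  fx <- gradient_fixture(n = 150, seed = 2)
  rootCluster <- fx$labels[which.min(fx$t)]
  tr1 <- order_cells(fx$coords, fx$labels, rootCluster)
  set.seed(3)
  perm <- sample(nrow(fx$coords))
  tr2 <- order_cells(fx$coords[perm, ], fx$labels[perm], rootCluster)
  expect_equal(tr2$pseudotime[names(tr1$pseudotime)], tr1$pseudotime,
               tolerance = 1e-10)
})

test_that("a Y-shaped embedding yields exactly two branches", {
  set.seed(4)
  n <- 80
  s <- seq(0.1, 2.5, length.out = n)
  trunk <- cbind(seq(0, 4, length.out = n), 0)
  armA <- cbind(4 + s, 2 * s)            # steep arms keep the MST Y-shaped
  armB <- cbind(4 + s, -2 * s)
  coords <- rbind(trunk, armA, armB) + matrix(rnorm(6 * n, sd = 0.15),
                                              3 * n, 2)
  rownames(coords) <- sprintf("c%04d", seq_len(3 * n))
  labels <- rep(c("t1", "t2", "a1", "a2", "b1", "b2"), each = n / 2)
  tr <- order_cells(coords, labels, "t1")
  expect_equal(n_branches(tr), 2L)
  expect_true(all(tr$branch[seq_len(n / 2)] == "trunk"))
})

test_that("two bifurcations in the centroid tree are rejected", {
  # H-shaped layout: two hubs, each with two 2-centroid arms
  pts <- rbind(c(0, 0), c(1, 0), c(2, 0), c(3, 0),     # spine
               c(0.5, 1), c(0.5, 2), c(2.5, 1), c(2.5, 2),
               c(0.5, -1), c(0.5, -2), c(2.5, -1), c(2.5, -2))
  set.seed(5)
  coords <- pts[rep(seq_len(nrow(pts)), each = 25), ] +
    matrix(rnorm(25 * nrow(pts) * 2, sd = 0.05), 25 * nrow(pts), 2)
  rownames(coords) <- sprintf("c%04d", seq_len(nrow(coords)))
  labels <- rep(seq_len(nrow(pts)), each = 25)
  expect_error(order_cells(coords, labels, 1), "more than one bifurcation")
})

test_that("spline DE finds planted trends and ignores flat genes", {
  set.seed(6)
  n <- 200
  pt <- runif(n)
  expr <- rbind(trend = log1p(rnbinom(n, mu = 4 * 2^pt, size = 8)),
                flat = log1p(rnbinom(n, mu = 6, size = 8)))
  colnames(expr) <- sprintf("c%03d", seq_len(n))
  out <- de_along_pseudotime(expr, pt, fdr = 0.1, returnAll = TRUE)
  expect_true(out$significant[out$gene == "trend"])
  expect_equal(eval(formals(de_along_pseudotime)$fdr), 0.1)
})

test_that("null genes stay below the FDR threshold in most replicates", {
  fp <- 0L
  for (r in 1:20) {
    set.seed(r + 100)
    n <- 100
    expr <- matrix(log1p(rnbinom(20 * n, mu = 5, size = 2)), 20, n,
                   dimnames = list(paste0("g", 1:20), NULL))
    colnames(expr) <- sprintf("c%03d", seq_len(n))
    sig <- de_along_pseudotime(expr, runif(n), fdr = 0.1)
    if (nrow(sig) > 0) fp <- fp + 1L
  }
  expect_lte(fp / 20, 0.25)
})

test_that("degenerate pseudotime inputs error", {
  expr <- matrix(rnorm(300), 3, 100,
                 dimnames = list(paste0("g", 1:3), sprintf("c%03d", 1:100)))
  expect_error(de_along_pseudotime(expr, rep(0.5, 100)), "constant")
  expect_error(de_along_pseudotime(expr[, 1:30], runif(30)), "50 cells")
})

test_that("two planted trend families give auto-k = 2", {
  set.seed(7)
  n <- 150
  pt <- sort(runif(n))
  rising <- t(sapply(1:20, function(i) 2 * pt + rnorm(n, sd = 0.2)))
  falling <- t(sapply(1:20, function(i) 2 * (1 - pt) + rnorm(n, sd = 0.2)))
  expr <- rbind(rising, falling)
  dimnames(expr) <- list(paste0("g", 1:40), sprintf("c%03d", 1:n))
  mods <- cluster_gene_trends(expr, pt, rownames(expr), k = "auto", seed = 1)
  expect_equal(mods$k, 2L)
  expect_length(unique(mods$modules[1:20]), 1L)
  expect_length(unique(mods$modules[21:40]), 1L)
})

test_that("fixed k = 4 partitions four planted templates cleanly", {
  cfg <- generator_config(nGenes = 400L, nTypes = 1L, cellsPerType = 300L,
                          markersPerType = 0L, baseMean = 2.5,
                          trajectory = list(nCells = 300L, nModules = 4L,
                                            genesPerModule = 20L))
  ds <- generate_trajectory(cfg, seed = 8)
  expr <- normalize_log(filter_genes(ds$counts, 10))
  pt <- ds$truePseudotime[colnames(expr)]
  genes <- intersect(names(ds$trueModule), rownames(expr))
  mods <- cluster_gene_trends(expr, pt, genes, k = 4, seed = 1)
  expect_equal(mods$k, 4L)
  ari <- adjusted_rand_index(mods$modules[genes], ds$trueModule[genes])
  expect_gte(ari, 0.9)
  # modules are ordered by peak position: module1 peaks earliest
  peaks <- vapply(sort(unique(mods$modules)), function(m) {
    mods$grid[which.max(rowMeans(mods$trends[, mods$modules == m,
                                             drop = FALSE]))]
  }, numeric(1))
  expect_true(!is.unsorted(peaks))
})

test_that("requesting more modules than genes errors", {
  expr <- matrix(rnorm(300), 3, 100,
                 dimnames = list(paste0("g", 1:3), sprintf("c%03d", 1:100)))
  expect_error(cluster_gene_trends(expr, runif(100), rownames(expr), k = 5),
               "fewer")
})

test_that("the root cluster is picked by progenitor-marker expression", {
  expr <- matrix(1, 2, 30, dimnames = list(c("sox2like", "other"),
                                           sprintf("c%03d", 1:30)))
  labels <- rep(c("A", "B", "C"), each = 10)
  expr["sox2like", labels == "B"] <- 5
  expect_equal(pick_root_cluster(expr, labels, "sox2like"), "B")
  expect_error(pick_root_cluster(expr, labels, "absent"), "no progenitor")
})
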