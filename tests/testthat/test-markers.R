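# log-normalized expression fixture with 3 planted groups
marker_fixture <- function(seed = 1, ...) {
  ds <- generate_celltypes(small_config(...), seed = seed)
  counts <- filter_genes(ds$counts, 10)
  list(expr = normalize_log(counts), labels = ds$cellType,
       markers = ds$trueMarkers, exclusives = ds$trueExclusives)
}

test_that("swapping groups negates avgLogFC and preserves p-values", {
  fx <- marker_fixture()
  A <- colnames(fx$expr)[fx$labels == "type01"]
  B <- colnames(fx$expr)[fx$labels == "type02"]
  ab <- de_two_groups(fx$expr, A, B)
  ba <- de_two_groups(fx$expr, B, A)
  common <- intersect(ab$gene, ba$gene)
  expect_gt(length(common), 0)
  expect_equal(ab$avgLogFC[match(common, ab$gene)],
               -ba$avgLogFC[match(common, ba$gene)])
  expect_equal(ab$pValue[match(common, ab$gene)],
               ba$pValue[match(common, ba$gene)])
})

test_that("Bonferroni adjustment is min(1, p * nTested)", {
  fx <- marker_fixture()
  A <- colnames(fx$expr)[fx$labels == "type01"]
  B <- colnames(fx$expr)[fx$labels != "type01"]
  rec <- de_two_groups(fx$expr, A, B)
  expect_equal(rec$adjP, pmin(1, rec$pValue * nrow(rec)))
  expect_true(all(rec$adjP >= rec$pValue))
})

test_that("the min.pct gate drops genes detected below threshold", {
  set.seed(2)
  expr <- matrix(0, 2, 80, dimnames = list(c("rare", "common"), NULL))
  colnames(expr) <- paste0("c", 1:80)
  expr["rare", sample(1:40, 4)] <- 2      # 10% of A
  expr["rare", 40 + sample(1:40, 2)] <- 2 # 5% of B
  expr["common", 1:40] <- rnorm(40, 3)
  expr["common", 41:80] <- rnorm(40, 1)
  rec <- de_two_groups(expr, paste0("c", 1:40), paste0("c", 41:80),
                       minPct = 0.25)
  expect_false("rare" %in% rec$gene)
  expect_true("common" %in% rec$gene)
})

test_that("a planted two-fold shift is detected in nearly all replicates", {
  hits <- 0L
  nRep <- 100L
  for (r in seq_len(nRep)) {
    set.seed(r)
    counts <- rbind(shifted = c(rnbinom(100, mu = 12, size = 4),
                                rnbinom(100, mu = 6, size = 4)),
                    matrix(rnbinom(19 * 200, mu = 6, size = 4), 19, 200))
    rownames(counts)[2:20] <- paste0("null", 1:19)
    colnames(counts) <- paste0("c", 1:200)
    expr <- log1p(counts)                 # equal-depth cells; direct log
    rec <- de_two_groups(expr, paste0("c", 1:100), paste0("c", 101:200),
                         minPct = 0, logfcThreshold = 0)
    if (rec$adjP[rec$gene == "shifted"] < 0.01) hits <- hits + 1L
  }
  expect_gte(hits / nRep, 0.95)
})

test_that("find_all_markers recovers planted markers with low pctOut", {
  fx <- marker_fixture()
  rec <- find_all_markers(fx$expr, fx$labels)
  pos <- rec[rec$positive, ]
  found <- vapply(names(fx$markers), function(g) {
    any(pos$gene == g & pos$cluster == fx$markers[[g]])
  }, logical(1))
  expect_gte(mean(found), 0.9)
})

test_that("top_markers orders by fold change and caps per cluster", {
  rec <- data.frame(gene = c("a", "b", "c", "d"),
                    avgLogFC = c(1, 2, 2, 0.5),
                    pctIn = 1, pctOut = 0,
                    pValue = c(1e-4, 1e-3, 1e-5, 1e-2),
                    adjP = c(1e-3, 1e-2, 1e-4, 1e-1),
                    cluster = "k1", positive = TRUE)
  top <- top_markers(rec, 25)
  expect_equal(nrow(top), 4L)                 # fewer records than n
  expect_equal(top$gene[1:2], c("c", "b"))    # tie on lfc -> adjP breaks it
  expect_equal(top_markers(rec, 2)$gene, c("c", "b"))
})

test_that("exclusivity screen enforces both detection gates", {
  expr <- matrix(0, 3, 60, dimnames = list(c("excl", "shared", "off"),
                                           paste0("c", 1:60)))
  labels <- rep(c("T", "U", "V"), each = 20)
  expr["excl", labels == "T"] <- c(rep(2, 18), 0, 0)   # 90% in target
  expr["excl", labels == "U"] <- c(2, rep(0, 19))      # 5% elsewhere
  expr["shared", labels %in% c("T", "U")] <- rep(c(2, 2, 0, 0, 2), 8)
  expr["off", labels == "V"] <- 2
  out <- exclusive_genes(expr, labels, "T", fOn = 0.3, fOff = 0.1)
  expect_identical(out, "excl")
  expect_error(exclusive_genes(expr, labels, "missing"), "not present")
})

test_that("planted exclusive genes are screened with high precision/recall", {
  fx <- marker_fixture(seed = 3, exclusivesPerType = 8L)
  out <- exclusive_genes(fx$expr, fx$labels, "type01", fOn = 0.3, fOff = 0.1)
  truthSet <- intersect(names(fx$exclusives)[fx$exclusives == "type01"],
                        rownames(fx$expr))
  expect_gte(mean(truthSet %in% out), 0.9)
  expect_gte(mean(out %in% truthSet), 0.9)
})

test_that("cluster-averaged z-scores match direct arithmetic on 4 cells", {
  expr <- matrix(c(1, 5, 2, 4,
                   3, 3, 3, 3), 2, 4, byrow = TRUE,
                 dimnames = list(c("g1", "g2"), paste0("c", 1:4)))
  labels <- c("A", "A", "B", "B")
  z <- suppressWarnings(celltype_zscore_matrix(expr, labels))
  x <- c(1, 5, 2, 4)
  zs <- (x - mean(x)) / sd(x)
  expect_equal(z["g1", "A"], mean(zs[1:2]))
  expect_equal(z["g1", "B"], mean(zs[3:4]))
  expect_equal(unname(z["g2", ]), c(0, 0))   # zero-variance row
})

test_that("a cluster-restricted gene has positive z only in its cluster", {
  expr <- matrix(0, 1, 30, dimnames = list("hc", paste0("c", 1:30)))
  labels <- rep(c("HC", "SC", "KO"), each = 10)
  expr["hc", labels == "HC"] <- 4
  z <- celltype_zscore_matrix(expr, labels)
  expect_gt(z["hc", "HC"], 0)
  expect_lt(z["hc", "SC"], 0)
  expect_lt(z["hc", "KO"], 0)
})

test_that("concordance counts eligible and matching directions", {
  records <- data.frame(gene = paste0("g", 1:10),
                        avgLogFC = c(rep(1, 8), -1, -1))
  refA <- setNames(c(9, 9, 9, 9, 9, 9, 9, 9, 1, 9), paste0("g", 1:10))
  refB <- setNames(c(1, 1, 1, 1, 1, 1, 1, 1, 9, 1), paste0("g", 1:10))
  # 8 up-genes concordant (ref fold 5), g9 down & ref down (concordant),
  # g10 down but ref up (discordant)
  out <- cross_dataset_concordance(records, refA, refB, foldThreshold = 2)
  expect_equal(out$nEligible, 10L)
  expect_equal(out$nConcordant, 9L)
  expect_equal(out$fraction, 0.9)
})

test_that("sub-threshold reference folds are ineligible; missing genes listed", {
  records <- data.frame(gene = c("a", "b"), avgLogFC = c(1, 1))
  refA <- c(a = 1.5)                       # fold (1.5+1)/(0+1) = 2.5? no:
  refB <- c(a = 1)                         # (1.5+1)/(1+1) = 1.25 < 2
  out <- cross_dataset_concordance(records, refA, refB, foldThreshold = 2)
  expect_equal(out$nEligible, 0L)
  expect_identical(out$notDetected, "b")
  expect_true(is.na(out$fraction))
})
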