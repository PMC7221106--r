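test_that("identical config and seed give identical counts", {
  cfg <- small_config()
  a <- generate_celltypes(cfg, seed = 3)
  b <- generate_celltypes(cfg, seed = 3)
  expect_identical(as.matrix(a$counts), as.matrix(b$counts))
  expect_identical(a$cellType, b$cellType)
  c <- generate_celltypes(cfg, seed = 4)
  expect_false(identical(as.matrix(a$counts), as.matrix(c$counts)))
})

test_that("planted gene roles are disjoint", {
  ds <- generate_regulon_data(small_config(), seed = 1)
  tfs <- names(ds$trueRegulons)
  targetSets <- lapply(ds$trueRegulons, `[[`, "targets")
  allTargets <- unlist(targetSets)
  expect_equal(anyDuplicated(allTargets), 0L)
  expect_length(intersect(allTargets, names(ds$trueMarkers)), 0L)
  expect_length(intersect(tfs, names(ds$trueMarkers)), 0L)
  byType <- split(names(ds$trueMarkers), ds$trueMarkers)
  expect_equal(anyDuplicated(unlist(byType)), 0L)
})

test_that("empirical marker fold matches the configured fold", {
  cfg <- generator_config(nGenes = 300L, nTypes = 3L, cellsPerType = 200L,
                          markersPerType = 8L, markerFold = 8)
  folds <- vapply(1:10, function(s) {
    ds <- generate_celltypes(cfg, seed = s)
    cnt <- as.matrix(ds$counts)
    ratios <- vapply(names(ds$trueMarkers), function(g) {
      own <- ds$cellType == ds$trueMarkers[[g]]
      mean(cnt[g, own]) / mean(cnt[g, !own])
    }, numeric(1))
    mean(ratios)
  }, numeric(1))
  expect_lt(abs(mean(folds) - 8), 0.25 * 8)
})

test_that("markerFold 1 plants no separation between types", {
  ds <- generate_celltypes(small_config(markerFold = 1), seed = 2)
  cnt <- as.matrix(ds$counts)
  lfc <- vapply(names(ds$trueMarkers), function(g) {
    own <- ds$cellType == ds$trueMarkers[[g]]
    log(mean(cnt[g, own]) + 0.1) - log(mean(cnt[g, !own]) + 0.1)
  }, numeric(1))
  expect_lt(mean(abs(lfc)), 0.15)
})

test_that("QC outlier injection corrupts exactly the requested cells", {
  cfg <- generator_config(nGenes = 500L, nTypes = 2L, cellsPerType = 50L,
                          markersPerType = 5L)
  ds <- generate_celltypes(cfg, seed = 5)
  out <- inject_qc_outliers(ds, c(low_complexity = 0.1), seed = 6)
  expect_length(out$qcViolations, 10L)
  cnt <- as.matrix(out$counts)
  for (cell in names(out$qcViolations)) {
    expect_lt(sum(cnt[, cell] > 0), 200)
    expect_lt(sum(cnt[, cell]), 1500)
  }
  untouched <- setdiff(colnames(cnt), names(out$qcViolations))
  expect_identical(cnt[, untouched], as.matrix(ds$counts)[, untouched])
})

test_that("high-mito injection pushes the recomputed mito share above 5%", {
  ds <- generate_celltypes(small_config(), seed = 8)
  out <- inject_qc_outliers(ds, c(high_mito = 0.05), seed = 9)
  cnt <- as.matrix(out$counts)
  mito <- grep("^mt-", rownames(cnt), value = TRUE)
  for (cell in names(out$qcViolations)) {
    share <- sum(cnt[mito, cell]) / sum(cnt[, cell])
    expect_gt(share, 0.05)
  }
})

test_that("zero fractions leave the dataset unchanged; unknown rules error", {
  ds <- generate_celltypes(small_config(), seed = 1)
  same <- inject_qc_outliers(ds, c(low_complexity = 0, high_mito = 0))
  expect_identical(as.matrix(same$counts), as.matrix(ds$counts))
  expect_error(inject_qc_outliers(ds, c(weird_rule = 0.1)), "weird_rule")
})

test_that("trend templates have the planted shapes", {
  f <- trend_template("early_decreasing", fold = 5)
  expect_equal(f(0) / f(1), 5)
  g <- trend_template("transient_peak", fold = 5)
  t <- seq(0, 1, length.out = 101)
  peakAt <- t[which.max(g(t))]
  expect_gt(peakAt, 0.05)
  expect_lt(peakAt, 0.95)
  expect_error(trend_template("nope", 2), "unknown trend template")
})

test_that("the trajectory preset plants four modules and uniform pseudotime", {
  ds <- generate_preset_dataset("trajectory", 2)
  expect_length(unique(ds$trueModule), 4L)
  expect_true(all(ds$truePseudotime >= 0 & ds$truePseudotime <= 1))
  # a planted transient-peak gene's smoothed profile has an interior max
  g <- names(ds$trueModule)[ds$trueModule == "module2"][1]
  lo <- lowess(ds$truePseudotime,
               as.matrix(ds$counts)[g, ], f = 0.3)
  peakAt <- lo$x[which.max(lo$y)]
  expect_gt(peakAt, 0.05)
  expect_lt(peakAt, 0.95)
})

test_that("timepoint pair records the exact planted up/down counts", {
  cfg <- small_config(pathways = list(nPathways = 2L, genesPerPathway = 4L,
                                      upFrac = 0.75, downFrac = 0.25))
  pair <- generate_timepoint_pair(cfg, seed = 1)
  expect_equal(pair$t1$truePathwayShift$nUp, c(3L, 3L))
  expect_equal(pair$t1$truePathwayShift$nDown, c(1L, 1L))
  expect_error(generate_timepoint_pair(
    small_config(pathways = list(shiftLogFC = -1)), 1), "shiftLogFC")
  expect_error(generate_timepoint_pair(
    small_config(pathways = list(upFrac = 0.8, downFrac = 0.5)), 1),
    "upFrac")
})

test_that("regulon coupling induces TF-target correlation in the active type", {
  cfg <- small_config(regulons = list(nTFs = 2L, targetsPerTF = 8L,
                                      couplingStrength = 0.8))
  hits <- 0L; total <- 0L
  for (s in 1:5) {
    ds <- generate_regulon_data(cfg, seed = s)
    cnt <- as.matrix(ds$counts)
    for (tf in names(ds$trueRegulons)) {
      reg <- ds$trueRegulons[[tf]]
      act <- ds$cellType == reg$activeType
      for (tg in reg$targets) {
        total <- total + 1L
        if (cor(cnt[tf, act], cnt[tg, act], method = "spearman") > 0.5)
          hits <- hits + 1L
      }
    }
  }
  expect_gte(hits / total, 0.9)
})

test_that("zero coupling leaves TF-target pairs uncorrelated", {
  cfg <- small_config(regulons = list(nTFs = 2L, targetsPerTF = 8L,
                                      couplingStrength = 0))
  ds <- generate_regulon_data(cfg, seed = 3)
  cnt <- as.matrix(ds$counts)
  cors <- unlist(lapply(names(ds$trueRegulons), function(tf) {
    reg <- ds$trueRegulons[[tf]]
    act <- ds$cellType == reg$activeType
    vapply(reg$targets, function(tg) {
      cor(cnt[tf, act], cnt[tg, act], method = "spearman")
    }, numeric(1))
  }))
  expect_lt(abs(median(cors)), 0.15)
})

test_that("impossible generator configurations are rejected", {
  expect_error(generator_config(nGenes = 10, nTypes = 3, markersPerType = 5),
               "exceeds nGenes")
  expect_error(generator_config(regulons = list(nTFs = 100L,
                                                targetsPerTF = 50L)),
               "half the genes")
})
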