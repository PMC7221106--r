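`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pipeline configuration
#'
#' Builds the full configuration for [run_pipeline()]; every default equals
#' the published analysis parameter it mirrors (QC bounds, resolution grid
#' 0.2-2.4 in 0.2 steps, min.pct 0.25, fold-change gate 0.25, pseudotime
#' FDR 0.1, pseudocell pool 5-20). A YAML file read with
#' [read_pipeline_config()] overrides any subset of keys.
#'
#' @param preset Name of a packaged generator preset (or NULL).
#' @param input Directory with a 10x-style matrix (or NULL).
#' @param out Output directory for artifact tables (or NULL for none).
#' @param seed Master seed; every stochastic stage derives its seed from it.
#' @param qc,normalize,cluster,markers,trajectory,regulons,metabolic Stage
#'   parameter lists; see the source for the keys.
#' @return A validated list of class `PipelineConfig`.
#' @export
pipeline_config <- function(preset = NULL, input = NULL, out = NULL,
                            seed = 1L,
                            qc = list(), normalize = list(), cluster = list(),
                            markers = list(), trajectory = list(),
                            regulons = list(), metabolic = list()) {
  defaults <- list(
    qc = list(minGenes = 200L, minUMI = 1500L, maxGenes = 3000L,
              maxUMI = 15000L, maxMitoFrac = 0.05, maxStressFrac = 0.05,
              minCellsPerGene = 10L, conjunctive = FALSE),
    normalize = list(scaleFactor = 1e4, clip = 10, nVariableGenes = 500L),
    cluster = list(nComponents = 20L, kNeighbors = 20L,
                   grid = seq(0.2, 2.4, by = 0.2),
                   selectionTolerance = 0.05, nTrees = 100L),
    markers = list(minPct = 0.25, logfcThreshold = 0.25, topN = 25L,
                   fOn = 0.3, fOff = 0.1),
    trajectory = list(fdr = 0.1, k = "auto", resolution = 1.6,
                      rootMarkers = NULL),
    regulons = list(poolMin = 5L, poolMax = 20L, nPerType = 50L,
                    topFraction = 0.05, corrThreshold = 0.3,
                    maxTargets = 50L, tfs = NULL, gmt = NULL),
    metabolic = list(alpha = 0.05, adjAlpha = 0.05, gmt = NULL))
  cfg <- list(preset = preset, input = input, out = out,
              seed = as.integer(seed),
              qc = utils::modifyList(defaults$qc, qc),
              normalize = utils::modifyList(defaults$normalize, normalize),
              cluster = utils::modifyList(defaults$cluster, cluster),
              markers = utils::modifyList(defaults$markers, markers),
              trajectory = utils::modifyList(defaults$trajectory, trajectory),
              regulons = utils::modifyList(defaults$regulons, regulons),
              metabolic = utils::modifyList(defaults$metabolic, metabolic))
  with(cfg$qc, stopifnot(minGenes >= 0, minUMI >= 0, minCellsPerGene >= 0,
                         minGenes < maxGenes, minUMI < maxUMI))
  stopifnot(!is.unsorted(cfg$cluster$grid, strictly = TRUE),
            cfg$regulons$poolMin >= 1,
            cfg$regulons$poolMin <= cfg$regulons$poolMax)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Keys present in the file override the defaults of [pipeline_config()].
#'
#' @param path YAML file.
#' @return A `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Generate the dataset a preset describes
#'
#' @param preset One of `"p1"`, `"p7"`, `"trajectory"`, `"regulons"`,
#'   `"timepoints"`.
#' @param seed Integer seed.
#' @return A `LabeledDataset` (a list of two for `"timepoints"`).
#' @export
generate_preset_dataset <- function(preset, seed = 1L) {
  cfg <- preset_config(preset)
  switch(preset,
    p1 = ,
    p7 = inject_qc_outliers(generate_celltypes(cfg, seed),
                            cfg$qcOutlierFractions, seed + 1L),
    trajectory = generate_trajectory(cfg, seed),
    regulons = generate_regulon_data(cfg, seed),
    timepoints = generate_timepoint_pair(cfg, seed),
    stop("unknown preset: ", preset, call. = FALSE))
}

.log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

.write_table <- function(df, path, provenance) {
  con <- file(path, "w")
  writeLines(paste0("# scCochlea ", provenance), con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
}

#' Gene and cell QC stage
#'
#' Applies the gene detection filter then the cell QC cascade.
#'
#' @param counts Genes-by-cells count matrix.
#' @param qcCfg The `qc` list of a [pipeline_config()].
#' @return List: `counts` (filtered), `report` (`QCReport`).
#' @export
qc_pipeline <- function(counts, qcCfg = pipeline_config()$qc) {
  counts <- filter_genes(counts, qcCfg$minCellsPerGene)
  th <- qc_thresholds(qcCfg$minGenes, qcCfg$minUMI, qcCfg$maxGenes,
                      qcCfg$maxUMI, qcCfg$maxMitoFrac, qcCfg$maxStressFrac,
                      qcCfg$minCellsPerGene, qcCfg$conjunctive)
  report <- filter_cells(counts, th)
  list(counts = retained_cells(counts, report), report = report)
}

#' Normalize, regress covariates, and scale
#'
#' Log-normalizes, selects highly variable genes, builds the per-cell
#' covariates (total UMI, mito and stress UMI shares) and regresses them
#' out before per-gene scaling. The scaled matrix is restricted to the
#' variable genes; `expr` keeps all genes.
#'
#' @param counts QC-passed genes-by-cells count matrix.
#' @param normCfg The `normalize` list of a [pipeline_config()].
#' @return List: `expr` (log-normalized, all genes), `scaled` (variable
#'   genes only), `variableGenes`, `covariates`.
#' @export
preprocess_pipeline <- function(counts, normCfg = pipeline_config()$normalize) {
  expr <- normalize_log(counts, normCfg$scaleFactor)
  hvg <- select_variable_genes(expr, normCfg$nVariableGenes %||% 500L)
  total <- Matrix::colSums(counts)
  mito <- grep("^mt-", rownames(counts), value = TRUE)
  stress <- grep("^stress-", rownames(counts), value = TRUE)
  cov <- cbind(
    totalUMI = as.numeric(total),
    mitoFrac = if (length(mito))
      as.numeric(Matrix::colSums(counts[mito, , drop = FALSE]) / total)
      else NULL,
    stressFrac = if (length(stress))
      as.numeric(Matrix::colSums(counts[stress, , drop = FALSE]) / total)
      else NULL)
  list(expr = expr,
       scaled = regress_and_scale(expr[hvg, , drop = FALSE], cov,
                                  normCfg$clip),
       variableGenes = hvg, covariates = cov)
}

#' QC-to-resolution-selection pipeline
#'
#' The full path from raw counts to a selected clustering: gene/cell QC,
#' log-normalization, covariate regression and scaling, PCA, and the
#' resolution scan with OOB-based selection.
#'
#' @param counts Genes-by-cells count matrix.
#' @param config A [pipeline_config()].
#' @return List: `qc`, `expr`, `scaled`, `embedding`, `scan`, `labels`
#'   (the selected clustering's labels).
#' @export
cluster_pipeline <- function(counts, config = pipeline_config()) {
  qc <- qc_pipeline(counts, config$qc)
  .log_stage("qc", "%d/%d cells retained, %d genes (seed %d)",
             qc$report$nAfter, qc$report$nBefore, nrow(qc$counts),
             config$seed)
  prep <- preprocess_pipeline(qc$counts, config$normalize)
  emb <- reduce_dims(prep$scaled, config$cluster$nComponents)
  scan <- scan_resolutions(emb, config$cluster$grid,
                           config$cluster$selectionTolerance,
                           config$cluster$kNeighbors,
                           config$cluster$nTrees, seed = config$seed)
  .log_stage("cluster", "selected %d clusters at resolution %.2f (seed %d)",
             scan$selected$nClusters, scan$selected$resolution, config$seed)
  list(qc = qc, expr = prep$expr, scaled = prep$scaled, embedding = emb,
       scan = scan, labels = scan$selected$labels)
}

#' Run the pipeline end to end
#'
#' Executes the stages in order qc -> cluster -> markers -> (trajectory |
#' regulons | metabolic) as applicable to the input, writing one CSV per
#' result table into `config$out` (if set) with a provenance header line,
#' and logging one line per stage to stderr. Deterministic given
#' `config$seed`.
#'
#' @param config A [pipeline_config()]; must name a `preset` or an `input`
#'   directory.
#' @param stages Character vector of stages, or `"all"`.
#' @return Invisible list of stage results.
#' @export
run_pipeline <- function(config, stages = "all") {
  if (is.null(config$preset) && is.null(config$input)) {
    stop("configuration error: no input matrix or generator preset named",
         call. = FALSE)
  }
  outDir <- config$out
  if (!is.null(outDir)) dir.create(outDir, recursive = TRUE,
                                   showWarnings = FALSE)
  results <- list()
  if (!is.null(config$preset)) {
    ds <- generate_preset_dataset(config$preset, config$seed)
    .log_stage("simulate", "preset %s (seed %d)", config$preset, config$seed)
  } else {
    ds <- list(counts = read_10x_mtx(config$input))
    class(ds) <- "LabeledDataset"
  }
  results$dataset <- ds
  if (identical(config$preset, "timepoints")) {
    if (any(stages %in% c("all", "metabolic"))) {
      prep1 <- preprocess_pipeline(filter_genes(ds$t1$counts,
                                                config$qc$minCellsPerGene),
                                   config$normalize)
      prep2 <- preprocess_pipeline(filter_genes(ds$t2$counts,
                                                config$qc$minCellsPerGene),
                                   config$normalize)
      ra <- regulation_analysis(prep1$expr, prep2$expr, ds$t1$cellType,
                                ds$t2$cellType, ds$t1$pathwaySets,
                                config$metabolic$alpha)
      .log_stage("metabolic", "%d pathways x %d types", nrow(ra$matrix),
                 ncol(ra$matrix))
      results$metabolic <- ra
      if (!is.null(outDir)) {
        m <- as.data.frame(unclass(ra$matrix))
        m <- cbind(pathway = rownames(ra$matrix), m)
        .write_table(m, file.path(outDir, "regulation_matrix.csv"),
          sprintf("regulation matrix (normalized pU - pD, unitless), preset %s seed %d",
                  config$preset, config$seed))
      }
    }
    return(invisible(results))
  }
  cp <- cluster_pipeline(ds$counts, config)
  results$cluster <- cp
  if (!is.null(outDir)) {
    .write_table(cp$qc$report$cells[, c("cell", "detectedGenes", "totalUMI",
                                        "mitoFrac", "stressFrac",
                                        "retained")],
                 file.path(outDir, "qc_report.csv"),
                 sprintf("per-cell QC (counts and UMI shares), seed %d",
                         config$seed))
    .write_table(cp$scan$table, file.path(outDir, "resolution_scan.csv"),
                 sprintf("resolution scan (OOB misclassification rate), seed %d",
                         config$seed))
    .write_table(data.frame(cell = names(cp$labels), cluster = cp$labels),
                 file.path(outDir, "cluster_labels.csv"),
                 sprintf("selected clustering at resolution %.2f, seed %d",
                         cp$scan$selected$resolution, config$seed))
  }
  if (any(stages %in% c("all", "markers"))) {
    rec <- find_all_markers(cp$expr, cp$labels, config$markers$minPct,
                            config$markers$logfcThreshold)
    top <- top_markers(rec, config$markers$topN)
    .log_stage("markers", "%d records, %d in top tables", nrow(rec),
               nrow(top))
    results$markers <- list(records = rec, top = top)
    if (!is.null(outDir)) {
      .write_table(rec, file.path(outDir, "markers.csv"),
        sprintf("one-vs-rest markers (natural-log fold change), seed %d",
                config$seed))
      .write_table(top, file.path(outDir, "top_markers.csv"),
        sprintf("top %d markers per cluster, seed %d",
                config$markers$topN, config$seed))
    }
  }
  if (any(stages %in% c("all", "trajectory")) &&
      identical(config$preset, "trajectory")) {
    labs <- cluster_at_resolution(cp$embedding,
                                  config$trajectory$resolution,
                                  config$cluster$kNeighbors,
                                  seed = config$seed)$labels
    rootMarkers <- config$trajectory$rootMarkers %||%
      grep("^mod1-", rownames(cp$expr), value = TRUE)
    root <- pick_root_cluster(cp$expr, labs, rootMarkers)
    traj <- order_cells(cp$embedding, labs, root)
    sig <- de_along_pseudotime(cp$expr, traj, config$trajectory$fdr)
    mods <- cluster_gene_trends(cp$expr, traj, sig$gene,
                                config$trajectory$k, seed = config$seed)
    .log_stage("trajectory", "%d significant genes, %d modules",
               nrow(sig), mods$k)
    results$trajectory <- list(trajectory = traj, significant = sig,
                               modules = mods)
    if (!is.null(outDir)) {
      .write_table(data.frame(cell = names(traj$pseudotime),
                              pseudotime = traj$pseudotime,
                              branch = traj$branch),
                   file.path(outDir, "pseudotime.csv"),
                   sprintf("pseudotime (normalized arc length), seed %d",
                           config$seed))
      .write_table(data.frame(gene = names(mods$modules),
                              module = mods$modules),
                   file.path(outDir, "gene_modules.csv"),
                   sprintf("phase-module assignments (k=%d), seed %d",
                           mods$k, config$seed))
    }
  }
  if (any(stages %in% c("all", "regulons")) &&
      !is.null(ds$trueRegulons %||% config$regulons$tfs %||%
               config$regulons$gmt)) {
    pcs <- make_pseudocells(cp$expr, cp$labels, config$regulons$poolMin,
                            config$regulons$poolMax,
                            config$regulons$nPerType, seed = config$seed)
    regs <- if (!is.null(config$regulons$gmt)) {
      read_gmt(config$regulons$gmt)
    } else {
      tfs <- config$regulons$tfs %||% names(ds$trueRegulons)
      infer_regulons(pcs, intersect(tfs, rownames(pcs$expr)),
                     config$regulons$corrThreshold,
                     config$regulons$maxTargets)
    }
    sc <- regulon_scores(pcs, regs, config$regulons$topFraction)
    .log_stage("regulons", "%d regulons x %d pseudocells", nrow(sc$RAS),
               ncol(sc$RAS))
    results$regulons <- list(pseudocells = pcs, regulons = regs, scores = sc)
    if (!is.null(outDir)) {
      .write_table(cbind(data.frame(regulon = rownames(sc$RSS)),
                         as.data.frame(sc$RSS)),
                   file.path(outDir, "rss.csv"),
                   sprintf("regulon specificity scores in [0,1], seed %d",
                           config$seed))
    }
  }
  invisible(results)
}
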