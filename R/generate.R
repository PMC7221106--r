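#' Generator configuration for synthetic cochlear-epithelium counts
#'
#' Builds and validates the parameter list consumed by the synthetic-data
#' generators. Counts are negative binomial with a gene-level mean scale and
#' a log-normal cell-level library-size factor, which reproduces the
#' overdispersion of UMI data. Mitochondrial and stress genes are named with
#' `mt-` / `stress-` prefixes so QC can locate them by convention.
#'
#' @param nGenes Total genes, including mito/stress genes.
#' @param nTypes Number of planted cell-type programs.
#' @param cellsPerType Cells per type (scalar or length-`nTypes` vector).
#' @param markersPerType Marker genes planted per type (disjoint across types).
#' @param markerFold Mean multiplier (> 1) on a marker gene in its own type.
#' @param exclusivesPerType Exclusively expressed genes planted per type:
#'   mean `baseMean` in the own type, `exclusiveOffMean` elsewhere.
#' @param exclusiveOffMean Out-of-type NB mean of exclusive genes (near 0,
#'   so detection elsewhere is a few percent at most).
#' @param baseMean Mean of the exponential distribution of per-gene NB means.
#' @param dispersion NB `size` parameter (inverse-dispersion; smaller = noisier).
#' @param libSizeSd Log-sd of the per-cell library-size factor (mean 1).
#' @param mitoGeneCount,stressGeneCount Number of `mt-` / `stress-` genes.
#' @param mitoFrac,stressFrac Target UMI share of mito / stress genes in a
#'   normal cell (the QC thresholds sit well above these).
#' @param qcOutlierFractions Named fractions for
#'   `c(low_complexity=, high_complexity=, high_mito=, high_stress=)`.
#' @param trajectory List: `nCells`, `nModules`, `genesPerModule`,
#'   `templates` (character; see [trend_template()]).
#' @param regulons List: `nTFs`, `targetsPerTF`, `couplingStrength`,
#'   optional `activeTypes` (type index per TF).
#' @param pathways List: `nPathways`, `genesPerPathway`, `upFrac`, `downFrac`
#'   (scalars or per-pathway vectors), `shiftLogFC` (natural log).
#' @param seed Default seed used when a generator call gives none.
#' @return A validated list of class `GeneratorConfig`.
#' @export
generator_config <- function(nGenes = 2000L, nTypes = 3L, cellsPerType = 100L,
                             markersPerType = 12L, markerFold = 6,
                             exclusivesPerType = 0L, exclusiveOffMean = 0.02,
                             baseMean = 1.5, dispersion = 2, libSizeSd = 0.2,
                             mitoGeneCount = 10L, stressGeneCount = 10L,
                             mitoFrac = 0.02, stressFrac = 0.02,
                             qcOutlierFractions = c(low_complexity = 0,
                                                    high_complexity = 0,
                                                    high_mito = 0,
                                                    high_stress = 0),
                             trajectory = list(nCells = 400L, nModules = 4L,
                                               genesPerModule = 25L,
                                               templates = NULL),
                             regulons = list(nTFs = 3L, targetsPerTF = 10L,
                                             couplingStrength = 0.8,
                                             activeTypes = NULL),
                             pathways = list(nPathways = 6L,
                                             genesPerPathway = 16L,
                                             upFrac = 0.5, downFrac = 0.25,
                                             shiftLogFC = log(2)),
                             seed = 1L) {
  qcOutlierFractions <- unlist(qcOutlierFractions)
  trajectory <- utils::modifyList(
    list(nCells = 400L, nModules = 4L, genesPerModule = 25L,
         templates = NULL), trajectory)
  regulons <- utils::modifyList(
    list(nTFs = 3L, targetsPerTF = 10L, couplingStrength = 0.8,
         activeTypes = NULL), regulons)
  pathways <- utils::modifyList(
    list(nPathways = 6L, genesPerPathway = 16L, upFrac = 0.5,
         downFrac = 0.25, shiftLogFC = log(2)), pathways)
  cfg <- list(nGenes = as.integer(nGenes), nTypes = as.integer(nTypes),
              cellsPerType = as.integer(cellsPerType),
              markersPerType = as.integer(markersPerType),
              exclusivesPerType = as.integer(exclusivesPerType),
              exclusiveOffMean = exclusiveOffMean,
              markerFold = markerFold, baseMean = baseMean,
              dispersion = dispersion, libSizeSd = libSizeSd,
              mitoGeneCount = as.integer(mitoGeneCount),
              stressGeneCount = as.integer(stressGeneCount),
              mitoFrac = mitoFrac, stressFrac = stressFrac,
              qcOutlierFractions = qcOutlierFractions,
              trajectory = trajectory, regulons = regulons,
              pathways = pathways, seed = as.integer(seed))
  if (cfg$markerFold < 1) stop("markerFold must be >= 1", call. = FALSE)
  if (cfg$nTypes * cfg$markersPerType > cfg$nGenes) {
    stop("nTypes * markersPerType exceeds nGenes", call. = FALSE)
  }
  if (any(cfg$qcOutlierFractions < 0) || any(cfg$qcOutlierFractions > 1)) {
    stop("qcOutlierFractions must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(cfg$regulons$nTFs) &&
      cfg$regulons$nTFs * cfg$regulons$targetsPerTF > cfg$nGenes / 2) {
    stop("regulon targets would occupy more than half the genes",
         call. = FALSE)
  }
  if (length(cfg$cellsPerType) == 1L) {
    cfg$cellsPerType <- rep(cfg$cellsPerType, cfg$nTypes)
  }
  stopifnot(length(cfg$cellsPerType) == cfg$nTypes)
  class(cfg) <- "GeneratorConfig"
  cfg
}

#' Load a packaged generator preset
#'
#' Presets mirror the structures reported for the real tissue: `p1`
#' (15 cell-type programs), `p7` (12 programs), `trajectory` (4 temporal
#' phase modules), `regulons` (TF-driven co-expression), `timepoints`
#' (two-time-point pathway shifts).
#'
#' @param name One of `"p1"`, `"p7"`, `"trajectory"`, `"regulons"`,
#'   `"timepoints"`.
#' @return A `GeneratorConfig`.
#' @export
preset_config <- function(name) {
  path <- system.file("presets", paste0(name, ".yaml"), package = "scCochlea")
  if (path == "") stop("unknown preset: ", name, call. = FALSE)
  vals <- yaml::read_yaml(path)
  do.call(generator_config, vals)
}

# NB sampler; coupled genes (regulons) are handled separately.
.sample_nb <- function(meanMat, size) {
  cnt <- stats::rnbinom(length(meanMat), size = size, mu = as.numeric(meanMat))
  matrix(cnt, nrow = nrow(meanMat), dimnames = dimnames(meanMat))
}

# truncated log-normal library-size factors (mean ~1). The truncation keeps
# ordinary cells inside the QC depth window, so the only QC violators in a
# generated dataset are the planted ones.
.lib_factors <- function(n, sdlog, lo = 0.6, hi = 1.8) {
  pmin(pmax(stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog), lo), hi)
}

# Allocate gene names/base means for one dataset. Special genes (markers,
# module genes, regulon genes, pathway genes) get the fixed baseMean so they
# are reliably detected; background genes draw from an exponential, whose
# low tail exercises the 10-cell gene filter.
.gene_table <- function(cfg, special) {
  nSpecial <- length(special)
  nBackground <- cfg$nGenes - nSpecial - cfg$mitoGeneCount -
    cfg$stressGeneCount
  if (nBackground < 0) stop("nGenes too small for planted gene roles",
                            call. = FALSE)
  genes <- c(special,
             if (nBackground > 0) sprintf("gene%05d", seq_len(nBackground)),
             if (cfg$mitoGeneCount > 0) sprintf("mt-%d",
                                                seq_len(cfg$mitoGeneCount)),
             if (cfg$stressGeneCount > 0)
               sprintf("stress-%d", seq_len(cfg$stressGeneCount)))
  means <- c(rep(cfg$baseMean, nSpecial),
             stats::rexp(nBackground, rate = 1 / cfg$baseMean))
  # mito/stress gene means sized so their expected UMI share ~= mitoFrac
  body <- sum(means)
  mito <- rep(cfg$mitoFrac / (1 - cfg$mitoFrac - cfg$stressFrac) * body /
                max(cfg$mitoGeneCount, 1L), cfg$mitoGeneCount)
  stress <- rep(cfg$stressFrac / (1 - cfg$mitoFrac - cfg$stressFrac) * body /
                  max(cfg$stressGeneCount, 1L), cfg$stressGeneCount)
  data.frame(gene = genes, mean = c(means, mito, stress),
             stringsAsFactors = FALSE)
}

.finish_dataset <- function(countMat, cellType, cfg, extra = list()) {
  counts <- Matrix::drop0(Matrix::Matrix(countMat, sparse = TRUE))
  names(cellType) <- colnames(counts)
  ds <- c(list(counts = counts, cellType = cellType,
               mitoGenes = grep("^mt-", rownames(counts), value = TRUE),
               stressGenes = grep("^stress-", rownames(counts), value = TRUE),
               qcViolations = list()),
          extra)
  class(ds) <- "LabeledDataset"
  ds
}

#' @export
print.LabeledDataset <- function(x, ...) {
  cat(sprintf("LabeledDataset: %d genes x %d cells, %d cell type(s)\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$cellType))))
  if (!is.null(x$trueMarkers))
    cat(sprintf("  planted markers: %d\n", length(x$trueMarkers)))
  if (!is.null(x$truePseudotime)) cat("  trajectory ground truth present\n")
  if (!is.null(x$trueRegulons))
    cat(sprintf("  planted regulons: %d\n", length(x$trueRegulons)))
  if (!is.null(x$truePathwayShift)) cat("  pathway-shift ground truth present\n")
  invisible(x)
}

#' Generate discrete cell-type programs
#'
#' Plants `nTypes` disjoint marker-gene programs: a marker gene's NB mean is
#' multiplied by `markerFold` in its own type. Mito/stress genes carry a
#' roughly 2\% UMI share in normal cells. Returns full ground truth for
#' recovery testing.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A `LabeledDataset`: `counts` (sparse genes x cells), `cellType`,
#'   `trueMarkers` (named character: gene -> type), mito/stress gene lists,
#'   empty `qcViolations`.
#' @export
generate_celltypes <- function(config, seed = config$seed) {
  cfg <- config
  set.seed(seed)
  types <- sprintf("type%02d", seq_len(cfg$nTypes))
  markers <- unlist(lapply(seq_len(cfg$nTypes), function(t) {
    sprintf("marker-%02d-%02d", t, seq_len(cfg$markersPerType))
  }))
  markerType <- rep(types, each = cfg$markersPerType)
  names(markerType) <- markers
  exclusives <- unlist(lapply(seq_len(cfg$nTypes), function(t) {
    if (cfg$exclusivesPerType > 0)
      sprintf("excl-%02d-%02d", t, seq_len(cfg$exclusivesPerType))
  }))
  exclusiveType <- stats::setNames(rep(types, each = cfg$exclusivesPerType),
                                   exclusives)
  gt <- .gene_table(cfg, c(markers, exclusives))
  nCells <- sum(cfg$cellsPerType)
  cellType <- rep(types, times = cfg$cellsPerType)
  lib <- .lib_factors(nCells, cfg$libSizeSd)
  meanMat <- outer(gt$mean, lib)
  for (t in seq_len(cfg$nTypes)) {
    cols <- which(cellType == types[t])
    rows <- match(names(markerType)[markerType == types[t]], gt$gene)
    meanMat[rows, cols] <- meanMat[rows, cols] * cfg$markerFold
    exRows <- match(names(exclusiveType)[exclusiveType == types[t]], gt$gene)
    if (length(exRows)) {
      meanMat[exRows, -cols] <- cfg$exclusiveOffMean *
        meanMat[exRows, -cols, drop = FALSE] / cfg$baseMean
    }
  }
  dimnames(meanMat) <- list(gt$gene, sprintf("cell%05d", seq_len(nCells)))
  counts <- .sample_nb(meanMat, cfg$dispersion)
  .finish_dataset(counts, cellType, cfg,
                  list(trueMarkers = markerType,
                       trueExclusives = exclusiveType, config = cfg))
}

#' Inject QC-violating cells
#'
#' Modifies randomly chosen cells so each violates exactly one QC rule:
#' `low_complexity` (< 200 detected genes and < 1,500 UMI),
#' `high_complexity` (total UMI pushed above the 15,000 bound),
#' `high_mito` / `high_stress` (UMI share raised to ~10\%, above the 5\%
#' bounds). Ground truth is recorded in `qcViolations`.
#'
#' @param ds A `LabeledDataset`.
#' @param fractions Named fractions of cells to corrupt per rule.
#' @param seed Integer seed.
#' @return The modified `LabeledDataset`.
#' @export
inject_qc_outliers <- function(ds, fractions = ds$config$qcOutlierFractions,
                               seed = ds$config$seed + 1L) {
  known <- c("low_complexity", "high_complexity", "high_mito", "high_stress")
  if (is.null(names(fractions)) || !all(names(fractions) %in% known)) {
    stop("unknown QC outlier rule: ",
         paste(setdiff(names(fractions), known), collapse = ", "),
         call. = FALSE)
  }
  if (all(fractions == 0)) return(ds)
  set.seed(seed)
  counts <- as.matrix(ds$counts)
  nCells <- ncol(counts)
  mito <- which(rownames(counts) %in% ds$mitoGenes)
  stress <- which(rownames(counts) %in% ds$stressGenes)
  special <- c(mito, stress)
  pool <- seq_len(nCells)
  viol <- ds$qcViolations
  for (rule in names(fractions)[fractions > 0]) {
    nPick <- round(fractions[[rule]] * nCells)
    if (nPick == 0) next
    pick <- sample(pool, nPick)
    pool <- setdiff(pool, pick)
    for (j in pick) {
      col <- counts[, j]
      if (rule == "low_complexity") {
        keep <- setdiff(which(col > 0), special)
        keep <- sample(keep, min(150L, length(keep)))
        new <- numeric(length(col))
        new[keep] <- col[keep]
        tot <- sum(new)
        if (tot >= 1500) {
          new[keep] <- stats::rbinom(length(keep), col[keep], 1000 / tot)
          new[keep[1L]] <- max(new[keep[1L]], 1)  # keep the cell nonempty
        }
        counts[, j] <- new
      } else if (rule == "high_complexity") {
        counts[, j] <- col * ceiling(18000 / max(sum(col), 1))
      } else if (rule == "high_mito") {
        target <- round(0.10 / 0.90 * sum(col[-mito]))
        counts[mito, j] <- as.numeric(
          stats::rmultinom(1L, max(target, 1L),
                           rep(1, length(mito))))
      } else if (rule == "high_stress") {
        target <- round(0.10 / 0.90 * sum(col[-stress]))
        counts[stress, j] <- as.numeric(
          stats::rmultinom(1L, max(target, 1L),
                           rep(1, length(stress))))
      }
      viol[[colnames(counts)[j]]] <- c(viol[[colnames(counts)[j]]], rule)
    }
  }
  ds$counts <- Matrix::drop0(Matrix::Matrix(counts, sparse = TRUE))
  ds$qcViolations <- viol
  ds
}

#' Temporal trend templates
#'
#' Multiplier curves over pseudotime `t` in `[0, 1]` used for module genes.
#' At its maximum each template multiplies the base mean by `fold`; away
#' from it the multiplier decays to 1. The four defaults mirror the phase
#' structure of outer-hair-cell development: genes switched off early,
#' transiently peaking, rising mid-trajectory, and rising late.
#'
#' @param name One of `"early_decreasing"`, `"transient_peak"`,
#'   `"mid_rising"`, `"late_rising"`.
#' @param fold Peak fold change (> 1).
#' @return A function of pseudotime returning mean multipliers.
#' @export
trend_template <- function(name, fold) {
  switch(name,
    early_decreasing = function(t) 1 + (fold - 1) * (1 - t),
    transient_peak   = function(t) 1 + (fold - 1) * exp(-((t - 0.3) / 0.1)^2),
    mid_rising       = function(t) 1 + (fold - 1) * stats::plogis((t - 0.45) / 0.06),
    late_rising      = function(t) 1 + (fold - 1) * pmax(0, (t - 0.65) / 0.35)^2,
    stop("unknown trend template: ", name, call. = FALSE))
}

#' Generate a differentiation continuum with temporal gene modules
#'
#' Cells receive a pseudotime drawn uniformly on `[0, 1]`; each module
#' gene's NB mean follows its template evaluated at the cell's pseudotime,
#' all other genes are flat.
#'
#' @param config A [generator_config()]; `config$trajectory` controls cell
#'   and module counts.
#' @param seed Integer seed.
#' @return `LabeledDataset` with `truePseudotime` and `trueModule`
#'   (named character: gene -> module id).
#' @export
generate_trajectory <- function(config, seed = config$seed) {
  cfg <- config
  tj <- cfg$trajectory
  if (tj$nModules < 2) stop("nModules must be >= 2", call. = FALSE)
  templates <- tj$templates
  if (is.null(templates)) {
    templates <- c("early_decreasing", "transient_peak", "mid_rising",
                   "late_rising")
  }
  templates <- rep_len(templates, tj$nModules)
  for (nm in templates) trend_template(nm, cfg$markerFold)  # validate names
  set.seed(seed)
  moduleGenes <- unlist(lapply(seq_len(tj$nModules), function(k) {
    sprintf("mod%d-%02d", k, seq_len(tj$genesPerModule))
  }))
  trueModule <- rep(sprintf("module%d", seq_len(tj$nModules)),
                    each = tj$genesPerModule)
  names(trueModule) <- moduleGenes
  gt <- .gene_table(cfg, moduleGenes)
  pt <- stats::runif(tj$nCells)
  lib <- .lib_factors(tj$nCells, cfg$libSizeSd)
  meanMat <- outer(gt$mean, lib)
  for (k in seq_len(tj$nModules)) {
    f <- trend_template(templates[k], cfg$markerFold)
    rows <- match(moduleGenes[trueModule == sprintf("module%d", k)], gt$gene)
    meanMat[rows, ] <- sweep(meanMat[rows, , drop = FALSE], 2, f(pt), `*`)
  }
  dimnames(meanMat) <- list(gt$gene, sprintf("cell%05d", seq_len(tj$nCells)))
  counts <- .sample_nb(meanMat, cfg$dispersion)
  .finish_dataset(counts, rep("trajectory", tj$nCells), cfg,
                  list(truePseudotime = stats::setNames(pt, colnames(counts)),
                       trueModule = trueModule,
                       moduleTemplates = stats::setNames(templates,
                         sprintf("module%d", seq_len(tj$nModules))),
                       config = cfg))
}

#' Generate TF-driven regulon co-expression
#'
#' On top of discrete cell-type programs, each transcription factor (TF) and
#' its disjoint target set share a cell-level latent activity factor within
#' the TF's active type: counts are Poisson given the factor, so the
#' factor itself carries the overdispersion and induces positive TF-target
#' correlation proportional to `couplingStrength`. Elsewhere the genes sit
#' at baseline.
#'
#' @param config A [generator_config()]; `config$regulons` controls TF
#'   number, targets and coupling.
#' @param seed Integer seed.
#' @return `LabeledDataset` with `trueRegulons`: a list per TF of
#'   `tf`, `targets`, `activeType`.
#' @export
generate_regulon_data <- function(config, seed = config$seed) {
  cfg <- config
  rg <- cfg$regulons
  set.seed(seed)
  types <- sprintf("type%02d", seq_len(cfg$nTypes))
  activeTypes <- rg$activeTypes
  if (is.null(activeTypes)) {
    activeTypes <- rep_len(seq_len(cfg$nTypes), rg$nTFs)
  }
  if (any(activeTypes < 1 | activeTypes > cfg$nTypes)) {
    stop("activeTypes out of range", call. = FALSE)
  }
  tfs <- sprintf("tf%d", seq_len(rg$nTFs))
  targets <- lapply(seq_len(rg$nTFs), function(k) {
    sprintf("tgt%d-%02d", k, seq_len(rg$targetsPerTF))
  })
  markers <- unlist(lapply(seq_len(cfg$nTypes), function(t) {
    sprintf("marker-%02d-%02d", t, seq_len(cfg$markersPerType))
  }))
  markerType <- stats::setNames(rep(types, each = cfg$markersPerType), markers)
  special <- c(tfs, unlist(targets), markers)
  gt <- .gene_table(cfg, special)
  nCells <- sum(cfg$cellsPerType)
  cellType <- rep(types, times = cfg$cellsPerType)
  lib <- .lib_factors(nCells, cfg$libSizeSd)
  meanMat <- outer(gt$mean, lib)
  for (t in seq_len(cfg$nTypes)) {
    rows <- match(names(markerType)[markerType == types[t]], gt$gene)
    cols <- which(cellType == types[t])
    meanMat[rows, cols] <- meanMat[rows, cols] * cfg$markerFold
  }
  dimnames(meanMat) <- list(gt$gene, sprintf("cell%05d", seq_len(nCells)))
  counts <- .sample_nb(meanMat, cfg$dispersion)
  # overwrite regulon genes: Poisson given a shared latent activity
  regulonRows <- lapply(seq_len(rg$nTFs), function(k) {
    match(c(tfs[k], targets[[k]]), gt$gene)
  })
  for (k in seq_len(rg$nTFs)) {
    rows <- regulonRows[[k]]
    active <- which(cellType == types[activeTypes[k]])
    act <- stats::rexp(nCells, rate = 1)
    amp <- numeric(nCells)
    amp[active] <- rg$couplingStrength * (cfg$markerFold - 1) * act[active]
    mu <- outer(rep(cfg$baseMean, length(rows)), lib * (1 + amp))
    counts[rows, ] <- matrix(stats::rpois(length(mu), as.numeric(mu)),
                             nrow = length(rows))
  }
  trueRegulons <- lapply(seq_len(rg$nTFs), function(k) {
    list(tf = tfs[k], targets = targets[[k]],
         activeType = types[activeTypes[k]])
  })
  names(trueRegulons) <- tfs
  .finish_dataset(counts, cellType, cfg,
                  list(trueMarkers = markerType, trueRegulons = trueRegulons,
                       config = cfg))
}

#' Generate a two-time-point pair with planted pathway shifts
#'
#' Draws two datasets with identical planted structure; in the second, a
#' per-pathway fraction `upFrac` of each pathway's genes has its mean
#' multiplied by `exp(shiftLogFC)` and `downFrac` divided by it. The exact
#' planted up/down counts are recorded in `truePathwayShift`.
#'
#' @param config A [generator_config()]; `config$pathways` controls sets and
#'   shift size.
#' @param seed Integer seed.
#' @return List of two `LabeledDataset`s (`t1`, `t2`); both carry
#'   `pathwaySets` and `truePathwayShift` (data frame: pathway, nUp, nDown,
#'   direction).
#' @export
generate_timepoint_pair <- function(config, seed = config$seed) {
  cfg <- config
  pw <- cfg$pathways
  if (pw$shiftLogFC <= 0) stop("shiftLogFC must be positive", call. = FALSE)
  upFrac <- rep_len(pw$upFrac, pw$nPathways)
  downFrac <- rep_len(pw$downFrac, pw$nPathways)
  if (any(upFrac + downFrac > 1)) {
    stop("upFrac + downFrac must be <= 1 per pathway", call. = FALSE)
  }
  pwNames <- sprintf("pathway%d", seq_len(pw$nPathways))
  pathwaySets <- lapply(seq_len(pw$nPathways), function(k) {
    sprintf("pw%d-%02d", k, seq_len(pw$genesPerPathway))
  })
  names(pathwaySets) <- pwNames
  nUp <- round(upFrac * pw$genesPerPathway)
  nDown <- pmin(pw$genesPerPathway - nUp, round(downFrac * pw$genesPerPathway))
  shift <- stats::setNames(rep(1, sum(lengths(pathwaySets))),
                           unlist(pathwaySets))
  for (k in seq_len(pw$nPathways)) {
    g <- pathwaySets[[k]]
    if (nUp[k] > 0) shift[g[seq_len(nUp[k])]] <- exp(pw$shiftLogFC)
    if (nDown[k] > 0) shift[g[nUp[k] + seq_len(nDown[k])]] <-
        exp(-pw$shiftLogFC)
  }
  truth <- data.frame(pathway = pwNames, nUp = nUp, nDown = nDown,
                      direction = sign(nUp - nDown))
  draw <- function(s, shiftVec) {
    set.seed(s)
    special <- unlist(pathwaySets)
    gt <- .gene_table(cfg, special)
    nCells <- sum(cfg$cellsPerType)
    types <- sprintf("type%02d", seq_len(cfg$nTypes))
    cellType <- rep(types, times = cfg$cellsPerType)
    lib <- .lib_factors(nCells, cfg$libSizeSd)
    means <- gt$mean
    if (!is.null(shiftVec)) {
      idx <- match(names(shiftVec), gt$gene)
      means[idx] <- means[idx] * shiftVec
    }
    meanMat <- outer(means, lib)
    dimnames(meanMat) <- list(gt$gene, sprintf("cell%05d", seq_len(nCells)))
    counts <- .sample_nb(meanMat, cfg$dispersion)
    .finish_dataset(counts, cellType, cfg,
                    list(pathwaySets = pathwaySets, truePathwayShift = truth,
                         config = cfg))
  }
  # the two time points use decorrelated sub-seeds from the same master seed
  list(t1 = draw(seed, NULL), t2 = draw(seed + 500000L, shift))
}
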