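# End-to-end orchestration: simulate -> preprocess -> DMD -> embed ->
# density (both directions) -> permutation inference -> report.
# Every stochastic stage derives its seed deterministically from the
# master seed, so a run is reproducible from its config alone.

#' Build a pipeline configuration
#'
#' @param synthetic a [syntheticConfig()] to simulate input cohorts, or
#'   `NULL` when reading real data via `manifestPath`.
#' @param manifestPath manifest TSV of an existing cohort (see
#'   [readCohort()]); ignored when `synthetic` is given.
#' @param discardSeconds initial seconds to drop per subject (default 0).
#' @param rankTol SVD truncation tolerance of the DMD (default 1e-10).
#' @param perplexity `"auto"` (select over `perplexityGrid` by peak
#'   separation) or a number.
#' @param perplexityGrid candidates for automatic selection.
#' @param tsneMaxIter t-SNE iterations.
#' @param sigmaGrid uLSIF kernel widths; `NULL` adapts the reference grid
#'   `c(1.2, 1.0, 0.8)` to the embedding scale ([scaledSigmaGrid()]).
#' @param etaGrid uLSIF ridge penalties (default 0.10, 0.09, ..., 0.01).
#' @param permSigma,permEta fixed kernel width and ridge penalty for the
#'   permutation null; `NULL` (default) reuses, per direction, the
#'   (sigma, eta) that cross-validation selected on the observed data —
#'   model selection is not repeated under the null.
#' @param gridResolution ratio/density evaluation grid nodes per axis.
#' @param marginFrac evaluation-grid margin per side.
#' @param nPerm number of permutations (default 100).
#' @param permutationLevel `"subject"` (default: cohort labels are
#'   shuffled across subjects, all of a subject's modes moving together)
#'   or `"mode"` (labels shuffled across individual pooled modes, the
#'   reference procedure). Modes of one subject are strongly dependent —
#'   conjugate pairs always carry the same label, and a subject's whole
#'   mode profile shifts with its active dynamics — so the mode-level
#'   null underdisperses and is anticonservative; subject-level
#'   shuffling is the calibrated default.
#' @param percentile significance percentile of the null maxima.
#' @param epsBoverA,minSamplesBoverA DBSCAN parameters for the
#'   B-enriched direction (reference values 1 and 100).
#' @param epsAoverB,minSamplesAoverB DBSCAN parameters for the
#'   A-enriched direction (reference values 0.15 and 300).
#' @param scaleClusterParams when `TRUE` (default) `eps` is multiplied by
#'   the embedding's median 10-NN distance and `minSamples` by
#'   `n / 160000` (floor 5), keeping the reference values meaningful for
#'   mode collections much smaller than the reference scale.
#' @param seed master seed of the run.
#' @return A list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(synthetic = syntheticConfig(),
                           manifestPath = NULL,
                           discardSeconds = 0,
                           rankTol = 1e-10,
                           perplexity = "auto",
                           perplexityGrid = c(10, 30, 100, 300),
                           tsneMaxIter = 1000L,
                           sigmaGrid = NULL,
                           etaGrid = seq(0.10, 0.01, by = -0.01),
                           permSigma = NULL,
                           permEta = NULL,
                           gridResolution = 200L,
                           marginFrac = 0.05,
                           nPerm = 100L,
                           permutationLevel = c("subject", "mode"),
                           percentile = 0.95,
                           epsBoverA = 1.0, minSamplesBoverA = 100L,
                           epsAoverB = 0.15, minSamplesAoverB = 300L,
                           scaleClusterParams = TRUE,
                           seed = 1L) {
  cfg <- list(synthetic = synthetic, manifestPath = manifestPath,
              discardSeconds = discardSeconds, rankTol = rankTol,
              perplexity = perplexity, perplexityGrid = perplexityGrid,
              tsneMaxIter = as.integer(tsneMaxIter),
              sigmaGrid = sigmaGrid, etaGrid = etaGrid,
              permSigma = permSigma, permEta = permEta,
              gridResolution = as.integer(gridResolution),
              marginFrac = marginFrac, nPerm = as.integer(nPerm),
              permutationLevel = match.arg(permutationLevel),
              percentile = percentile,
              epsBoverA = epsBoverA,
              minSamplesBoverA = as.integer(minSamplesBoverA),
              epsAoverB = epsAoverB,
              minSamplesAoverB = as.integer(minSamplesAoverB),
              scaleClusterParams = isTRUE(scaleClusterParams),
              seed = as.integer(seed))
  class(cfg) <- "PipelineConfig"
  problems <- validateConfig(cfg)
  if (length(problems))
    stop("invalid pipeline configuration:\n  ",
         paste(problems, collapse = "\n  "))
  cfg
}

#' Validate a pipeline configuration
#'
#' @param cfg a `"PipelineConfig"` (or a plain list with its fields).
#' @return Character vector of problems; empty when runnable.
#' @export
validateConfig <- function(cfg) {
  p <- character()
  if (is.null(cfg$synthetic) && is.null(cfg$manifestPath))
    p <- c(p, "either a synthetic config or a manifest path is required")
  if (!is.null(cfg$synthetic))
    p <- c(p, validateSyntheticConfig(cfg$synthetic))
  if (!identical(cfg$perplexity, "auto")) {
    if (!is.numeric(cfg$perplexity) || cfg$perplexity <= 0)
      p <- c(p, "perplexity must be \"auto\" or a positive number")
    else if (!is.null(cfg$synthetic)) {
      # upper bound on usable perplexity given the maximal mode count
      nMax <- 2L * cfg$synthetic$nSubjectsPerGroup *
        min(2L * cfg$synthetic$nRoi, cfg$synthetic$nTimepoints - 2L)
      if (3 * cfg$perplexity >= nMax - 1)
        p <- c(p, "perplexity too large for the number of modes")
    }
  } else if (length(cfg$perplexityGrid) == 0L) {
    p <- c(p, "perplexity grid must be nonempty for automatic selection")
  }
  if (!is.null(cfg$sigmaGrid) && length(cfg$sigmaGrid) == 0L)
    p <- c(p, "sigma grid must be nonempty")
  if (length(cfg$etaGrid) == 0L || any(cfg$etaGrid <= 0))
    p <- c(p, "eta grid must be nonempty and positive")
  if (is.null(cfg$nPerm) || cfg$nPerm < 1L)
    p <- c(p, "nPerm must be at least 1")
  if (cfg$percentile <= 0 || cfg$percentile >= 1)
    p <- c(p, "percentile must lie in (0, 1)")
  if (cfg$epsBoverA <= 0 || cfg$epsAoverB <= 0)
    p <- c(p, "DBSCAN eps values must be positive")
  if (cfg$gridResolution < 50L)
    p <- c(p, "grid resolution must be at least 50")
  p
}

#' Run the full pipeline
#'
#' Executes simulate (when configured) -> preprocess -> DMD -> embedding
#' -> per-cohort KDE -> density-ratio estimation in both directions ->
#' permutation inference -> clustering -> report, writing all artifacts
#' under `outDir`. Deterministic for a fixed config (including the master
#' seed).
#'
#' Artifacts: `cohort/` (subject TSVs + manifest + ground truth),
#' `modes.tsv`, `mode_vectors.tsv`, `embedding.tsv`, per-cohort density
#' fields, per-direction ratio fields and CV scores, `null_maxima_*.tsv`,
#' `thresholds.json`, `cluster_assignments.tsv`, per-cluster summary
#' TSVs, `report.json`, `run_manifest.json` (config hash and stage
#' parameters) and `run_log.txt`.
#'
#' @param cfg a [pipelineConfig()].
#' @param outDir run directory (created if missing).
#' @return Invisibly, a list with the pooled [ModeSet-class], ratio
#'   models, permutation results, clusters, summaries and `outDir`.
#' @export
runPipeline <- function(cfg, outDir) {
  stopifnot(inherits(cfg, "PipelineConfig") || is.list(cfg))
  problems <- validateConfig(cfg)
  if (length(problems))
    stop("invalid pipeline configuration:\n  ",
         paste(problems, collapse = "\n  "))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(outDir, "run_log.txt")
  logLine <- function(stage, ...) {
    cat(sprintf("[%s] %s %s\n", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                stage, paste0(...)), file = logPath, append = TRUE)
  }
  stage <- "simulate"
  result <- tryCatch({
    # --- inputs -----------------------------------------------------------
    groundTruth <- NULL
    if (!is.null(cfg$synthetic)) {
      simCfg <- cfg$synthetic
      simCfg$seed <- stageSeed(cfg$seed, "simulate")
      cohort <- generateCohort(simCfg)
      subjects <- cohort$subjects
      groundTruth <- cohort$groundTruth
      writeCohort(cohort, file.path(outDir, "cohort"))
      logLine(stage, sprintf("%d subjects simulated", length(subjects)))
    } else {
      subjects <- readCohort(cfg$manifestPath)
      logLine(stage, sprintf("%d subjects read from %s", length(subjects),
                             cfg$manifestPath))
    }

    stage <- "preprocess"
    subjects <- lapply(subjects, preprocessSubject,
                       discardSeconds = cfg$discardSeconds)
    logLine(stage, "detrend + confound regression + z-score done")

    stage <- "dmd"
    dmds <- dmdCohort(subjects, rankTol = cfg$rankTol)
    modeSet <- poolModes(dmds)
    writeModeTable(modeSet, outDir)
    logLine(stage, sprintf("%d modes pooled", length(modeSet)))

    stage <- "embed"
    embedSeed <- stageSeed(cfg$seed, "embed")
    if (identical(cfg$perplexity, "auto")) {
      sel <- selectPerplexity(modeSet, grid = cfg$perplexityGrid,
                              seed = embedSeed, maxIter = cfg$tsneMaxIter)
      modeSet <- sel$embedded
      logLine(stage, sprintf("perplexity %g selected (scores: %s)",
                             sel$perplexity,
                             paste(sel$scores, collapse = ", ")))
    } else {
      modeSet <- embedModes(modeSet, perplexity = cfg$perplexity,
                            seed = embedSeed, maxIter = cfg$tsneMaxIter)
      logLine(stage, sprintf("perplexity %g", cfg$perplexity))
    }
    writeEmbeddingTable(modeSet, file.path(outDir, "embedding.tsv"))

    stage <- "density"
    coords <- modeEmbedding(modeSet)
    groups <- modeSet@info$group
    grid <- makeGrid(coords, resolution = cfg$gridResolution,
                     marginFrac = cfg$marginFrac)
    for (g in c("A", "B")) {
      dens <- kdeFit(coords[groups == g, , drop = FALSE])
      writeFieldTable(densityFieldOf(dens, grid),
                      file.path(outDir, sprintf("density_%s.tsv", g)))
    }
    sigmaGrid <- cfg$sigmaGrid
    if (is.null(sigmaGrid)) sigmaGrid <- scaledSigmaGrid(coords)
    densitySeed <- stageSeed(cfg$seed, "density")
    ratios <- list()
    for (dir in c("BoverA", "AoverB")) {
      numG <- if (dir == "BoverA") "B" else "A"
      num <- coords[groups == numG, , drop = FALSE]
      den <- coords[groups != numG, , drop = FALSE]
      fit <- ulsifFit(num, den, sigmaGrid = sigmaGrid, etaGrid = cfg$etaGrid,
                      seed = densitySeed, direction = dir)
      ratios[[dir]] <- fit
      writeFieldTable(ratioField(fit, grid),
                      file.path(outDir, sprintf("ratio_%s.tsv", dir)))
      utils::write.table(fit@cvScores,
                         file.path(outDir, sprintf("cv_scores_%s.tsv", dir)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      logLine(stage, sprintf("%s: sigma=%g eta=%g", dir, fit@sigma, fit@eta))
    }

    stage <- "infer"
    s <- if (cfg$scaleClusterParams) medianKnnDistance(coords, 10L) else 1
    clusterParams <- list(
      BoverA = list(eps = cfg$epsBoverA * s,
                    minSamples = if (cfg$scaleClusterParams)
                      max(5L, as.integer(round(cfg$minSamplesBoverA *
                                                 length(modeSet) / 160000)))
                    else cfg$minSamplesBoverA),
      AoverB = list(eps = cfg$epsAoverB * s,
                    minSamples = if (cfg$scaleClusterParams)
                      max(5L, as.integer(round(cfg$minSamplesAoverB *
                                                 length(modeSet) / 160000)))
                    else cfg$minSamplesAoverB))
    permSeed <- stageSeed(cfg$seed, "infer")
    perms <- list(); clusters <- list(); thresholds <- list()
    assignRows <- list()
    permParams <- list()
    for (dir in c("BoverA", "AoverB")) {
      numG <- if (dir == "BoverA") "B" else "A"
      permSigma <- if (is.null(cfg$permSigma)) ratios[[dir]]@sigma
                   else cfg$permSigma
      permEta <- if (is.null(cfg$permEta)) ratios[[dir]]@eta else cfg$permEta
      permParams[[dir]] <- c(sigma = permSigma, eta = permEta)
      blocks <- if (identical(cfg$permutationLevel, "subject"))
        modeSet@info$subjectId else NULL
      perm <- permutationNull(coords, groups, numeratorGroup = numG,
                              sigma = permSigma, eta = permEta,
                              grid = grid, nPerm = cfg$nPerm,
                              seed = stageSeed(permSeed, dir),
                              percentile = cfg$percentile,
                              blocks = blocks)
      perms[[dir]] <- perm
      thresholds[[dir]] <- perm$threshold
      utils::write.table(
        data.frame(perm = seq_along(perm$nullMaxPeaks),
                   max_peak = perm$nullMaxPeaks),
        file.path(outDir, sprintf("null_maxima_%s.tsv", dir)),
        sep = "\t", quote = FALSE, row.names = FALSE)
      sig <- significantModes(modeSet, ratios[[dir]], perm$threshold)
      cl <- buildClusters(modeSet, sig,
                          eps = clusterParams[[dir]]$eps,
                          minSamples = clusterParams[[dir]]$minSamples,
                          direction = dir)
      clusters[[dir]] <- cl
      logLine(stage, sprintf(
        "%s: threshold=%.4f, %d significant modes, %d cluster(s)",
        dir, perm$threshold, length(sig), length(cl)))
      for (clust in cl)
        assignRows[[paste(dir, clust$clusterId)]] <- data.frame(
          mode_row = clust$members,
          subject_id = modeSet@info$subjectId[clust$members],
          group = modeSet@info$group[clust$members],
          mode_index = modeSet@info$modeIndex[clust$members],
          direction = dir, cluster_id = clust$clusterId)
    }
    assignments <- if (length(assignRows)) do.call(rbind, assignRows)
      else data.frame(mode_row = integer(0), subject_id = character(0),
                      group = character(0), mode_index = integer(0),
                      direction = character(0), cluster_id = integer(0))
    rownames(assignments) <- NULL
    utils::write.table(assignments,
                       file.path(outDir, "cluster_assignments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(thresholds, file.path(outDir, "thresholds.json"),
                         auto_unbox = TRUE, digits = NA)

    stage <- "report"
    dt <- if (!is.null(cfg$synthetic)) cfg$synthetic$dt
          else samplingInterval(dmds[[1]])
    summaries <- list()
    for (dir in names(clusters))
      for (clust in clusters[[dir]])
        summaries[[length(summaries) + 1L]] <-
          clusterSummary(clust, modeSet, dt)
    writeReport(summaries, outDir)
    logLine(stage, sprintf("%d cluster summaries written", length(summaries)))

    # --- run manifest -----------------------------------------------------
    cfgPath <- file.path(outDir, "config.yaml")
    writePipelineConfig(cfg, cfgPath)
    jsonlite::write_json(
      list(configHash = as.character(tools::md5sum(cfgPath)),
           nSubjects = length(subjects), nModes = length(modeSet),
           sigmaGrid = sigmaGrid, permParams = permParams,
           clusterParams = clusterParams,
           thresholds = thresholds,
           artifacts = list.files(outDir, recursive = TRUE)),
      file.path(outDir, "run_manifest.json"), auto_unbox = TRUE,
      digits = NA, pretty = TRUE)

    invisible(list(modeSet = modeSet, ratios = ratios, permutations = perms,
                   clusters = clusters, summaries = summaries,
                   groundTruth = groundTruth, assignments = assignments,
                   thresholds = thresholds, outDir = outDir))
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  result
}

#' Write / read a pipeline configuration as YAML
#'
#' Configurations round-trip losslessly through YAML.
#'
#' @param cfg a `"PipelineConfig"`.
#' @param path file path.
#' @return `writePipelineConfig`: invisibly, `path`;
#'   `readPipelineConfig`: the configuration.
#' @export
writePipelineConfig <- function(cfg, path) {
  x <- unclass(cfg)
  if (!is.null(x$synthetic)) x$synthetic <- unclass(x$synthetic)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$synthetic)) {
    x$synthetic <- do.call(syntheticConfig, x$synthetic)
  }
  syn <- x$synthetic
  x$synthetic <- NULL
  do.call(pipelineConfig, c(list(synthetic = syn), x))
}
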