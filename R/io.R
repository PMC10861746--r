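# Plain-text I/O: subject TSVs, cohort manifest, ground truth JSON,
# pooled-mode and embedding tables.

#' Write a cohort to disk
#'
#' One tab-delimited file per subject (rows = ROIs, columns = time
#' points, no header), an ROI-label sidecar, optional per-subject
#' confound TSVs (header row with column names), a cohort manifest TSV
#' (subject_id, group, dt, protocol, file, confound_file) and, when
#' ground truth is supplied, `ground_truth.json`.
#'
#' @param cohort list as returned by [generateCohort()], or a list with
#'   just `subjects`.
#' @param outDir output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
writeCohort <- function(cohort, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  subjects <- cohort$subjects
  rows <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    file <- sprintf("%s.tsv", s@subjectId)
    utils::write.table(s@data, file.path(outDir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    confFile <- ""
    if (ncol(s@confounds) > 0L) {
      confFile <- sprintf("%s_confounds.tsv", s@subjectId)
      utils::write.table(s@confounds, file.path(outDir, confFile),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = TRUE)
    }
    rows[[i]] <- data.frame(subject_id = s@subjectId, group = s@group,
                            dt = s@dt, protocol = s@protocol, file = file,
                            confound_file = confFile,
                            stringsAsFactors = FALSE)
  }
  nroi <- nrow(subjects[[1]]@data)
  utils::write.table(data.frame(roi = seq_len(nroi),
                                label = sprintf("ROI%03d", seq_len(nroi))),
                     file.path(outDir, "roi_labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- file.path(outDir, "manifest.tsv")
  utils::write.table(do.call(rbind, rows), manifest, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$groundTruth)) {
    gt <- cohort$groundTruth
    jsonlite::write_json(
      list(spatialPatterns = gt$spatialPatterns,
           activeModes = gt$activeModes,
           occurrenceProbA = gt$occurrenceProbA,
           occurrenceProbB = gt$occurrenceProbB,
           differentialModes = gt$differentialModes),
      file.path(outDir, "ground_truth.json"), digits = NA)
  }
  invisible(manifest)
}

#' Read a cohort from a manifest
#'
#' @param manifestPath path to a manifest TSV written by [writeCohort()]
#'   (columns subject_id, group, dt, protocol, file, optional
#'   confound_file; file paths relative to the manifest).
#' @return List of [ROITimeSeries-class] objects.
#' @export
readCohort <- function(manifestPath) {
  man <- utils::read.delim(manifestPath, stringsAsFactors = FALSE)
  base <- dirname(manifestPath)
  lapply(seq_len(nrow(man)), function(i) {
    X <- as.matrix(utils::read.delim(file.path(base, man$file[i]),
                                     header = FALSE))
    dimnames(X) <- NULL
    conf <- matrix(0, ncol(X), 0L)
    cf <- if ("confound_file" %in% names(man)) man$confound_file[i] else ""
    if (!is.na(cf) && nzchar(cf)) {
      conf <- as.matrix(utils::read.delim(file.path(base, cf), header = TRUE))
    }
    ROITimeSeries(X, dt = man$dt[i], subjectId = man$subject_id[i],
                  group = man$group[i], protocol = man$protocol[i],
                  confounds = conf)
  })
}

#' Write the pooled modes table
#'
#' Emits `modes.tsv` (subject_id, group, protocol, mode_index,
#' eigenvalue_real, eigenvalue_imag, frequency_hz) plus
#' `mode_vectors.tsv`, one row per mode holding the first-`Nroi` complex
#' entries as alternating real/imag columns.
#'
#' @param modeSet a [ModeSet-class].
#' @param outDir output directory.
#' @return Invisibly, the modes table path.
#' @export
writeModeTable <- function(modeSet, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  info <- modeSet@info
  utils::write.table(
    data.frame(subject_id = info$subjectId, group = info$group,
               protocol = info$protocol, mode_index = info$modeIndex,
               eigenvalue_real = info$eigRe, eigenvalue_imag = info$eigIm,
               frequency_hz = info$frequencyHz),
    file.path(outDir, "modes.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  H <- modeSet@halfModes
  vec <- matrix(0, nrow(H), 2L * ncol(H))
  vec[, seq(1L, 2L * ncol(H), by = 2L)] <- Re(H)
  vec[, seq(2L, 2L * ncol(H), by = 2L)] <- Im(H)
  colnames(vec) <- paste0(rep(c("re", "im"), ncol(H)),
                          rep(seq_len(ncol(H)), each = 2L))
  utils::write.table(vec, file.path(outDir, "mode_vectors.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file.path(outDir, "modes.tsv"))
}

#' Write the embedding table
#'
#' `embedding.tsv`: subject_id, group, protocol, mode_index, x, y,
#' frequency_hz, eigenvalue_real, eigenvalue_imag.
#'
#' @param modeSet an embedded [ModeSet-class].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
writeEmbeddingTable <- function(modeSet, path) {
  emb <- modeEmbedding(modeSet)
  info <- modeSet@info
  utils::write.table(
    data.frame(subject_id = info$subjectId, group = info$group,
               protocol = info$protocol, mode_index = info$modeIndex,
               x = emb[, 1], y = emb[, 2],
               frequency_hz = info$frequencyHz,
               eigenvalue_real = info$eigRe, eigenvalue_imag = info$eigIm),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a density or ratio field as TSV
#'
#' Long format: x, y, value — one row per grid node.
#'
#' @param field a `"DensityField"`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
writeFieldTable <- function(field, path) {
  nodes <- gridNodes(field$grid)
  utils::write.table(data.frame(x = nodes[, 1], y = nodes[, 2],
                                value = as.numeric(field$values)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
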