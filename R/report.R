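# Per-cluster summaries: mean amplitude and circular mean phase per ROI,
# frequency histogram, eigenvalues, cohort composition, per-protocol
# normalized counts.

#' Summarize one cluster of dynamic modes
#'
#' Per ROI, the mean amplitude is the arithmetic mean over members of the
#' entry moduli, and the phase is the circular mean of the entry
#' arguments (amplitudes and phases are averaged separately because
#' conjugate-paired modes would cancel under naive complex averaging).
#' A phase is flagged undefined (and set to 0) when the circular
#' resultant length falls below 0.1. The frequency histogram uses |f|
#' (folding conjugate-pair frequencies) in fixed 0.01 Hz bins from 0 to
#' Nyquist. Eigenvalues are passed through for unit-circle inspection.
#'
#' @param cluster one cluster from [buildClusters()].
#' @param modeSet the embedded [ModeSet-class] the cluster refers to.
#' @param dt sampling interval in seconds (sets the Nyquist bound of the
#'   frequency histogram).
#' @return A list of class `"ClusterSummary"`.
#' @export
clusterSummary <- function(cluster, modeSet, dt) {
  stopifnot(is(modeSet, "ModeSet"))
  members <- cluster$members
  if (length(members) == 0L) stop("empty cluster")
  H <- modeSet@halfModes[members, , drop = FALSE]      # n x Nroi complex
  amp <- colMeans(Mod(H))
  unitPhases <- exp(1i * Arg(H))
  resultant <- colMeans(unitPhases)
  phaseDefined <- Mod(resultant) >= 0.1
  phase <- ifelse(phaseDefined, Arg(resultant), 0)
  nyq <- 1 / (2 * dt)
  breaks <- seq(0, ceiling(nyq / 0.01) * 0.01 + 1e-12, by = 0.01)
  f <- abs(modeSet@info$frequencyHz[members])
  hist <- graphics::hist(f, breaks = breaks, right = FALSE, plot = FALSE)
  eig <- complex(real = modeSet@info$eigRe[members],
                 imaginary = modeSet@info$eigIm[members])
  structure(list(
    clusterId = cluster$clusterId,
    direction = cluster$direction,
    size = length(members),
    meanAmplitude = amp,
    circularPhase = phase,
    phaseDefined = phaseDefined,
    freqBreaks = breaks,
    freqCounts = hist$counts,
    meanAbsFrequencyHz = mean(f),
    eigenvalues = eig,
    groupComposition = table(modeSet@info$group[members]),
    protocolCounts = protocolNormalizedCounts(cluster, modeSet),
    centroid = cluster$centroid
  ), class = "ClusterSummary")
}

#' Per-protocol normalized mode counts
#'
#' For every protocol present in the pooled mode collection: the number
#' of cluster members acquired under that protocol divided by the total
#' number of pooled modes from that protocol. Protocols absent from the
#' cluster map to 0.
#'
#' @param cluster one cluster from [buildClusters()].
#' @param modeSet the [ModeSet-class] the cluster refers to.
#' @return Named numeric vector, one entry per protocol.
#' @export
protocolNormalizedCounts <- function(cluster, modeSet) {
  stopifnot(is(modeSet, "ModeSet"))
  protos <- sort(unique(modeSet@info$protocol))
  total <- table(factor(modeSet@info$protocol, levels = protos))
  inCl <- table(factor(modeSet@info$protocol[cluster$members],
                       levels = protos))
  out <- as.numeric(inCl) / as.numeric(total)
  names(out) <- protos
  out
}

#' Write cluster summaries to disk
#'
#' Emits, per cluster: `cluster_<id>_<direction>_amplitude.tsv`
#' (roi, mean_amplitude, circular_phase, phase_defined),
#' `..._freq_hist.tsv` (bin_lo, bin_hi, count) and
#' `..._eigenvalues.tsv` (re, im); plus `protocol_counts.tsv` across
#' clusters and a machine-readable `report.json` digest.
#'
#' @param summaries list of `"ClusterSummary"` objects.
#' @param outDir output directory (created if missing).
#' @return Invisibly, the path of `report.json`.
#' @export
writeReport <- function(summaries, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  protoRows <- list()
  digest <- list(nClusters = length(summaries), clusters = list())
  for (s in summaries) {
    tag <- sprintf("cluster_%d_%s", s$clusterId, gsub("[^A-Za-z0-9]", "",
                                                      s$direction))
    utils::write.table(
      data.frame(roi = seq_along(s$meanAmplitude),
                 mean_amplitude = s$meanAmplitude,
                 circular_phase = s$circularPhase,
                 phase_defined = s$phaseDefined),
      file.path(outDir, paste0(tag, "_amplitude.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    nb <- length(s$freqCounts)
    utils::write.table(
      data.frame(bin_lo = s$freqBreaks[seq_len(nb)],
                 bin_hi = s$freqBreaks[seq_len(nb) + 1L],
                 count = s$freqCounts),
      file.path(outDir, paste0(tag, "_freq_hist.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(re = Re(s$eigenvalues), im = Im(s$eigenvalues)),
      file.path(outDir, paste0(tag, "_eigenvalues.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    protoRows[[tag]] <- data.frame(cluster = tag,
                                   protocol = names(s$protocolCounts),
                                   normalized_count =
                                     as.numeric(s$protocolCounts))
    digest$clusters[[tag]] <- list(
      clusterId = s$clusterId, direction = s$direction, size = s$size,
      centroid = as.numeric(s$centroid),
      groupComposition = as.list(s$groupComposition),
      meanAbsFrequencyHz = s$meanAbsFrequencyHz)
  }
  if (length(protoRows))
    utils::write.table(do.call(rbind, protoRows),
                       file.path(outDir, "protocol_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  path <- file.path(outDir, "report.json")
  jsonlite::write_json(digest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
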