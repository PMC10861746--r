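# Max-statistic permutation test on the density-ratio surface and
# clustering of significant modes.

#' Maximum of a field
#'
#' @param field a `"DensityField"` (from [ratioField()] or
#'   [densityFieldOf()]).
#' @return The maximum value over the grid nodes.
#' @export
maxPeak <- function(field) {
  stopifnot(inherits(field, "DensityField"), length(field$values) > 0L)
  max(field$values)
}

#' Permutation null of the maximum ratio peak
#'
#' Shuffles the cohort labels of the embedded modes (group sizes
#' preserved), refits uLSIF in the requested direction at fixed
#' (sigma, eta) — model selection is not repeated under the null — and
#' records the maximum of the ratio surface over the grid; repeated
#' `nPerm` times. The significance threshold is the 95th percentile of
#' the null maxima under the linear-interpolation percentile rule.
#'
#' @param coords embedding coordinates (`n x 2`).
#' @param labels cohort labels (two levels) aligned with `coords`.
#' @param numeratorGroup label whose density forms the numerator.
#' @param sigma,eta fixed kernel width and ridge penalty.
#' @param grid a `"GridSpec"` on which maxima are evaluated.
#' @param nPerm number of permutations (>= 1; default 100).
#' @param seed integer seed.
#' @param percentile threshold percentile (default 0.95).
#' @param nCenters kernel centers per fit (default 100).
#' @param blocks optional blocking factor (e.g. subject ids) aligned with
#'   `coords`. When given, labels are shuffled at the block level — every
#'   mode of a block keeps its block's permuted label — which respects
#'   within-block dependence; the default (`NULL`) shuffles at the mode
#'   level, mirroring the reference procedure.
#' @return A list of class `"PermutationResult"`: `nullMaxPeaks`,
#'   `threshold`, `nPerm`, `fixedParams`, `seed`, `direction`.
#' @export
permutationNull <- function(coords, labels, numeratorGroup, sigma, eta,
                            grid, nPerm = 100L, seed = 0L,
                            percentile = 0.95, nCenters = 100L,
                            blocks = NULL) {
  coords <- as.matrix(coords)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L)
    stop("both cohort labels must be present")
  nPerm <- stopifnotScalarCount(nPerm, "nPerm")
  if (!is.null(blocks)) {
    blocks <- as.character(blocks)
    blockIds <- unique(blocks)
    blockLabel <- labels[match(blockIds, blocks)]
    if (any(tapply(labels, blocks, function(l) length(unique(l))) > 1L))
      stop("labels must be constant within a block")
  }
  nullMax <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(nPerm), function(p) {
      perm <- if (is.null(blocks)) sample(labels)
              else sample(blockLabel)[match(blocks, blockIds)]
      num <- coords[perm == numeratorGroup, , drop = FALSE]
      den <- coords[perm != numeratorGroup, , drop = FALSE]
      fit <- ulsifFitFixed(num, den, sigma = sigma, eta = eta,
                           seed = sample.int(2147483629, 1L),
                           nCenters = nCenters)
      maxPeak(ratioField(fit, grid))
    }, numeric(1))
  })
  structure(list(nullMaxPeaks = nullMax,
                 threshold = as.numeric(quantile(nullMax, percentile,
                                                 type = 7)),
                 nPerm = nPerm,
                 fixedParams = c(alpha = 0, sigma = sigma, eta = eta),
                 seed = as.integer(seed),
                 percentile = percentile,
                 direction = paste0(numeratorGroup, "-enriched")),
            class = "PermutationResult")
}

#' Modes in significant ratio regions
#'
#' Returns the indices of modes whose own embedded coordinate has an
#' observed density ratio strictly above the threshold.
#'
#' @param modeSet an embedded [ModeSet-class].
#' @param ratioModel the observed-data [RatioModel-class].
#' @param threshold significance threshold (from [permutationNull()]).
#' @return Integer vector of mode indices (rows of the [ModeSet-class]).
#' @export
significantModes <- function(modeSet, ratioModel, threshold) {
  stopifnot(is(modeSet, "ModeSet"))
  r <- ratioPredict(ratioModel, modeEmbedding(modeSet))
  which(r > threshold)
}

#' Cluster significant modes
#'
#' Runs DBSCAN on the embedded coordinates of the significant modes,
#' discards noise points, and numbers clusters by decreasing size (ties:
#' earlier-seeded cluster first).
#'
#' @param modeSet an embedded [ModeSet-class].
#' @param sigIdx indices of significant modes ([significantModes()]).
#' @param eps,minSamples DBSCAN parameters.
#' @param direction label recorded on each cluster (which ratio
#'   direction the significance came from).
#' @return A list of clusters; each is a list with `clusterId`,
#'   `members` (mode indices into the [ModeSet-class]), `direction`,
#'   `centroid` (2-D), `size`.
#' @export
buildClusters <- function(modeSet, sigIdx, eps, minSamples,
                          direction = "enriched") {
  stopifnot(is(modeSet, "ModeSet"))
  if (length(sigIdx) == 0L) return(list())
  coords <- modeEmbedding(modeSet)[sigIdx, , drop = FALSE]
  labels <- dbscanLabels(coords, eps = eps, minSamples = minSamples)
  ids <- setdiff(sort(unique(labels)), 0L)
  if (length(ids) == 0L) return(list())
  sizes <- vapply(ids, function(k) sum(labels == k), integer(1))
  ord <- order(-sizes, ids)
  out <- vector("list", length(ids))
  for (j in seq_along(ord)) {
    k <- ids[ord[j]]
    members <- sigIdx[labels == k]
    out[[j]] <- list(clusterId = j,
                     members = members,
                     direction = direction,
                     centroid = colMeans(
                       modeEmbedding(modeSet)[members, , drop = FALSE]),
                     size = length(members))
  }
  out
}
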