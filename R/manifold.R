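# Pooling modes into real feature vectors and embedding them in 2-D.
#
# Only the first Nroi entries of each delay-stacked mode are used (the
# second block is redundant up to the one-step propagator), split into
# real and imaginary parts and stacked: an exact linear isometry of the
# complex half-mode.

#' Feature vector of one dynamic mode
#'
#' Takes the first `Nroi` of the `2*Nroi` complex mode entries and
#' concatenates real parts followed by imaginary parts.
#'
#' @param dmd a [DMDResult-class].
#' @param modeIndex column index of the mode.
#' @return Numeric feature vector of length `2*Nroi`.
#' @export
modeToFeature <- function(dmd, modeIndex) {
  stopifnot(is(dmd, "DMDResult"))
  if (modeIndex < 1L || modeIndex > ncol(dmd@modes))
    stop("mode index out of range")
  half <- dmd@modes[seq_len(dmd@nRoi), modeIndex]
  c(Re(half), Im(half))
}

#' Pool dynamic modes from many subjects
#'
#' Stacks all modes of all subjects into one [ModeSet-class] for joint
#' manifold analysis, carrying provenance (subject, cohort, protocol,
#' frequency, eigenvalue) per mode.
#'
#' @param dmdResults list of [DMDResult-class] objects (equal `nRoi`).
#' @return A [ModeSet-class].
#' @export
poolModes <- function(dmdResults) {
  stopifnot(length(dmdResults) > 0L)
  nroi <- unique(vapply(dmdResults, function(d) d@nRoi, integer(1)))
  if (length(nroi) != 1L)
    stop("all subjects must share the same number of ROIs")
  halves <- lapply(dmdResults, function(d)
    t(d@modes[seq_len(d@nRoi), , drop = FALSE]))
  halfModes <- do.call(rbind, halves)
  info <- do.call(rbind, lapply(dmdResults, function(d) {
    k <- ncol(d@modes)
    data.frame(subjectId = rep(d@subjectId, k), group = rep(d@group, k),
               protocol = rep(d@protocol, k), modeIndex = seq_len(k),
               frequencyHz = d@frequencies, eigRe = Re(d@eigenvalues),
               eigIm = Im(d@eigenvalues), stringsAsFactors = FALSE)
  }))
  rownames(info) <- NULL
  new("ModeSet", halfModes = halfModes,
      features = cbind(Re(halfModes), Im(halfModes)),
      info = info, embedding = matrix(0, 0L, 2L), nRoi = nroi)
}

#' Embed pooled modes on a two-dimensional manifold
#'
#' Runs t-SNE on the mode feature vectors: 2-D coordinates minimizing the
#' Kullback-Leibler divergence between high-dimensional and embedding
#' neighbour distributions at the given perplexity. Deterministic given
#' `seed`; record order is preserved.
#'
#' @param modeSet a [ModeSet-class].
#' @param perplexity t-SNE perplexity; must satisfy
#'   `3 * perplexity < n - 1` for `n` pooled modes.
#' @param seed integer seed.
#' @param maxIter t-SNE iterations (default 1000).
#' @param theta Barnes-Hut accuracy/speed trade-off (default 0.5; 0 runs
#'   exact t-SNE).
#' @return The [ModeSet-class] with its `embedding` slot filled.
#' @export
embedModes <- function(modeSet, perplexity = 30, seed = 0L, maxIter = 1000L,
                       theta = 0.5) {
  stopifnot(is(modeSet, "ModeSet"))
  n <- nrow(modeSet@features)
  if (perplexity <= 0 || 3 * perplexity >= n - 1)
    stop(sprintf(
      "invalid configuration: perplexity %g needs at least %d points (have %d)",
      perplexity, ceiling(3 * perplexity + 2), n))
  fit <- withr::with_seed(as.integer(seed),
    Rtsne::Rtsne(modeSet@features, dims = 2, perplexity = perplexity,
                 theta = theta, max_iter = as.integer(maxIter),
                 check_duplicates = FALSE, pca = TRUE, verbose = FALSE,
                 num_threads = 1L))
  emb <- fit$Y
  dimnames(emb) <- NULL
  initialize(modeSet, embedding = emb)
}

#' Count separated density peaks of a 2-D point cloud
#'
#' Automated stand-in for visual inspection of manifold quality: fits the
#' pooled Gaussian KDE, evaluates it on a `resolution x resolution` grid
#' over the bounding box, and counts local maxima whose height exceeds
#' `heightFrac` of the global maximum and which are at least `minSep` grid
#' cells away from any higher counted peak.
#'
#' @param coords numeric matrix (`n x 2`), `n >= 10`.
#' @param resolution grid nodes per axis (default 100).
#' @param heightFrac minimum peak height as a fraction of the global
#'   maximum (default 0.2).
#' @param minSep minimum separation between counted peaks, in grid cells
#'   (default 2).
#' @return Number of distinct peaks (nonnegative integer).
#' @export
peakSeparationScore <- function(coords, resolution = 100L, heightFrac = 0.2,
                                minSep = 2L) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 10L) stop("at least 10 points are required")
  grid <- makeGrid(coords, resolution = resolution, marginFrac = 0.05)
  dens <- kdeFit(coords)
  field <- matrix(kdeEvaluate(dens, gridNodes(grid)), resolution, resolution)
  peaks <- localMaxima(field)
  peaks <- peaks[field[peaks] > heightFrac * max(field), , drop = FALSE]
  if (nrow(peaks) == 0L) return(0L)
  ord <- order(field[peaks], decreasing = TRUE)
  peaks <- peaks[ord, , drop = FALSE]
  kept <- matrix(0L, 0L, 2L)
  for (i in seq_len(nrow(peaks))) {
    p <- peaks[i, , drop = FALSE]
    if (nrow(kept) == 0L ||
        all(pmax(abs(kept[, 1] - p[1]), abs(kept[, 2] - p[2])) >= minSep))
      kept <- rbind(kept, p)
  }
  nrow(kept)
}

# row/col indices of grid nodes >= all 8 neighbours (plateau-tolerant)
localMaxima <- function(field) {
  nr <- nrow(field); nc <- ncol(field)
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- field
  isMax <- matrix(TRUE, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    nb <- pad[(2:(nr + 1L)) + di, (2:(nc + 1L)) + dj]
    isMax <- isMax & (field >= nb)
  }
  which(isMax, arr.ind = TRUE)
}

#' Select a perplexity maximizing peak separation
#'
#' Embeds the pooled modes at each candidate perplexity and returns the
#' one whose embedding shows the largest number of separated density
#' peaks ([peakSeparationScore()]); ties go to the smallest perplexity.
#'
#' @param modeSet a [ModeSet-class].
#' @param grid nonempty numeric vector of candidate perplexities.
#' @param seed integer seed (shared across candidates).
#' @param ... passed on to [embedModes()].
#' @return A list with `perplexity` (the choice), `scores` (per
#'   candidate), and `embedded` (the [ModeSet-class] embedded at the
#'   chosen value).
#' @export
selectPerplexity <- function(modeSet, grid = c(10, 30, 100, 300), seed = 0L,
                             ...) {
  if (length(grid) == 0L) stop("perplexity grid must be nonempty")
  grid <- sort(unique(grid))
  n <- nrow(modeSet@features)
  usable <- grid[3 * grid < n - 1]
  if (length(usable) == 0L)
    stop("no perplexity in the grid is usable for this sample size")
  embedded <- lapply(usable, function(p)
    embedModes(modeSet, perplexity = p, seed = seed, ...))
  scores <- vapply(embedded, function(ms)
    peakSeparationScore(ms@embedding), numeric(1))
  best <- which.max(scores)  # ties: first = smallest (grid sorted)
  list(perplexity = usable[best], scores = setNames(scores, usable),
       embedded = embedded[[best]])
}
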