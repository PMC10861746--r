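# Synthetic two-cohort generator.
#
# Subjects are superpositions of damped/stable oscillatory spatial modes:
#   X[, t] = sum_{m active} c_m * r_m^t * cos(2*pi*f_m*dt*t + theta_m) * v_m
#            + L %*% t(C)[, t] + noise
# Each mode m is active in a subject with its cohort's occurrence
# probability, so cohorts differ in how often modes occur, not in the
# modes themselves. This is exactly the hypothesis class of the
# delay-stacked DMD downstream, with known ground truth for recovery tests.

#' Configuration of the synthetic two-cohort generator
#'
#' @param nRoi number of ROIs (default 60).
#' @param nTimepoints number of time points per subject (default 150).
#' @param dt sampling interval in seconds (default 2).
#' @param nModes number of planted oscillatory modes (default 6).
#' @param frequencies per-mode frequencies in Hz, strictly below Nyquist
#'   `1/(2*dt)`.
#' @param decayRates per-mode per-step amplitude ratios in (0, 1]; 1 is a
#'   stable oscillation, below 1 a decaying one.
#' @param occurrenceProbA,occurrenceProbB per-mode activation
#'   probabilities in cohorts A and B.
#' @param amplitudeScale center of the per-subject mode amplitude range;
#'   amplitudes are drawn uniformly from `[0.5, 1.5] * amplitudeScale`.
#' @param noiseSd standard deviation of the i.i.d. Gaussian sensor noise.
#' @param nSubjectsPerGroup subjects per cohort.
#' @param nConfounds number of slow nuisance series (random walks) mixed
#'   into every subject.
#' @param protocol protocol tag stamped on the subjects.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return A validated list of class `"SyntheticConfig"`.
#' @examples
#' cfg <- syntheticConfig(nRoi = 12, nTimepoints = 60,
#'                        nSubjectsPerGroup = 3, seed = 1)
#' @export
syntheticConfig <- function(nRoi = 60L,
                            nTimepoints = 150L,
                            dt = 2.0,
                            nModes = 6L,
                            frequencies = c(0.02, 0.05, 0.08, 0.12, 0.16,
                                            0.20),
                            decayRates = c(1, 0.99, 1, 0.98, 0.99, 0.97),
                            occurrenceProbA = rep(0.5, 6L),
                            occurrenceProbB = rep(0.5, 6L),
                            amplitudeScale = 1.0,
                            noiseSd = 0.2,
                            nSubjectsPerGroup = 20L,
                            nConfounds = 2L,
                            protocol = "sim",
                            seed = 1L) {
  cfg <- list(nRoi = as.integer(nRoi), nTimepoints = as.integer(nTimepoints),
              dt = dt, nModes = as.integer(nModes),
              frequencies = frequencies, decayRates = decayRates,
              occurrenceProbA = occurrenceProbA,
              occurrenceProbB = occurrenceProbB,
              amplitudeScale = amplitudeScale, noiseSd = noiseSd,
              nSubjectsPerGroup = as.integer(nSubjectsPerGroup),
              nConfounds = as.integer(nConfounds),
              protocol = as.character(protocol), seed = as.integer(seed))
  class(cfg) <- "SyntheticConfig"
  problems <- validateSyntheticConfig(cfg)
  if (length(problems))
    stop("invalid synthetic configuration:\n  ",
         paste(problems, collapse = "\n  "))
  cfg
}

validateSyntheticConfig <- function(cfg) {
  p <- character()
  if (cfg$nRoi < 1L) p <- c(p, "nRoi must be positive")
  if (cfg$nTimepoints < 4L) p <- c(p, "nTimepoints must be at least 4")
  if (cfg$dt <= 0) p <- c(p, "dt must be positive")
  if (cfg$nModes < 1L) p <- c(p, "nModes must be positive")
  if (cfg$nModes > cfg$nRoi) p <- c(p, "nModes must not exceed nRoi")
  nyq <- 1 / (2 * cfg$dt)
  if (length(cfg$frequencies) != cfg$nModes)
    p <- c(p, "frequencies must have length nModes")
  else if (any(cfg$frequencies <= 0) || any(cfg$frequencies >= nyq))
    p <- c(p, sprintf("frequencies must lie strictly inside (0, %g) Hz", nyq))
  if (length(cfg$decayRates) != cfg$nModes)
    p <- c(p, "decayRates must have length nModes")
  else if (any(cfg$decayRates <= 0) || any(cfg$decayRates > 1))
    p <- c(p, "decayRates must lie in (0, 1]")
  for (nm in c("occurrenceProbA", "occurrenceProbB")) {
    pr <- cfg[[nm]]
    if (length(pr) != cfg$nModes)
      p <- c(p, sprintf("%s must have length nModes", nm))
    else if (any(pr < 0) || any(pr > 1))
      p <- c(p, sprintf("%s must lie in [0, 1]", nm))
  }
  if (cfg$amplitudeScale <= 0) p <- c(p, "amplitudeScale must be positive")
  if (cfg$noiseSd < 0) p <- c(p, "noiseSd must be nonnegative")
  if (cfg$nSubjectsPerGroup < 1L)
    p <- c(p, "nSubjectsPerGroup must be positive")
  if (cfg$nConfounds < 0L) p <- c(p, "nConfounds must be nonnegative")
  p
}

#' Block-structured unit-norm spatial patterns
#'
#' Divides the ROIs into `nModes` contiguous blocks. Pattern m is 1 on its
#' block, with a small random spill-over into the neighbouring blocks'
#' edge ROIs, then normalized to unit Euclidean norm. Patterns mimic
#' localized network-like topographies and are nearly orthogonal
#' (pairwise correlations stay below 0.5).
#'
#' @param nRoi number of ROIs.
#' @param nModes number of patterns; must not exceed `nRoi`.
#' @param seed integer seed.
#' @param overlap fraction of spill-over weight (default 0.15); 0 gives
#'   exactly disjoint blocks.
#' @return A list of `nModes` numeric unit-norm vectors of length `nRoi`.
#' @examples
#' p <- makeSpatialPatterns(4, 2, seed = 1, overlap = 0)
#' @export
makeSpatialPatterns <- function(nRoi, nModes, seed = 1L, overlap = 0.15) {
  nRoi <- stopifnotScalarCount(nRoi, "nRoi")
  nModes <- stopifnotScalarCount(nModes, "nModes")
  if (nModes > nRoi)
    stop("invalid configuration: nModes must not exceed nRoi")
  withr::with_seed(as.integer(seed), {
    edges <- round(seq(0L, nRoi, length.out = nModes + 1L))
    lapply(seq_len(nModes), function(m) {
      v <- numeric(nRoi)
      v[(edges[m] + 1L):edges[m + 1L]] <- 1
      if (overlap > 0) {
        if (m > 1L) v[edges[m]] <- v[edges[m]] + runif(1, 0, overlap)
        if (m < nModes)
          v[edges[m + 1L] + 1L] <- v[edges[m + 1L] + 1L] + runif(1, 0, overlap)
      }
      v / sqrt(sum(v^2))
    })
  })
}

#' Slow nuisance series
#'
#' Generates `nConfounds` centered random-walk series (cumulative sums of
#' white noise), emulating the low-frequency content of motion and
#' physiological nuisance regressors.
#'
#' @param nTimepoints number of rows.
#' @param nConfounds number of columns (0 gives an empty matrix).
#' @param seed integer seed.
#' @return Numeric matrix `nTimepoints x nConfounds`, columns centered.
#' @export
generateConfounds <- function(nTimepoints, nConfounds, seed = 1L) {
  nTimepoints <- stopifnotScalarCount(nTimepoints, "nTimepoints")
  if (nConfounds == 0L)
    return(matrix(0, nTimepoints, 0L))
  withr::with_seed(as.integer(seed), {
    C <- apply(matrix(rnorm(nTimepoints * nConfounds), nTimepoints,
                      nConfounds), 2L, cumsum)
    C <- matrix(C, nTimepoints, nConfounds)
    scale(C, center = TRUE, scale = FALSE)[, , drop = FALSE]
  })
}

# Draw one subject using the *current* RNG state (callers seed).
drawSubject <- function(cfg, group, patterns, subjectId) {
  probs <- if (group == "A") cfg$occurrenceProbA else cfg$occurrenceProbB
  active <- which(runif(cfg$nModes) < probs)
  tIdx <- 0:(cfg$nTimepoints - 1L)
  X <- matrix(0, cfg$nRoi, cfg$nTimepoints)
  for (m in active) {
    cm <- runif(1, 0.5 * cfg$amplitudeScale, 1.5 * cfg$amplitudeScale)
    th <- runif(1, 0, 2 * pi)
    wave <- cm * cfg$decayRates[m]^tIdx *
      cos(2 * pi * cfg$frequencies[m] * cfg$dt * tIdx + th)
    X <- X + outer(patterns[[m]], wave)
  }
  conf <- matrix(0, cfg$nTimepoints, 0L)
  if (cfg$nConfounds > 0L) {
    conf <- generateConfounds(cfg$nTimepoints, cfg$nConfounds,
                              seed = sample.int(2147483629, 1L))
    loadings <- matrix(rnorm(cfg$nRoi * cfg$nConfounds, sd = 0.5),
                       cfg$nRoi, cfg$nConfounds)
    X <- X + loadings %*% t(conf)
    colnames(conf) <- paste0("conf", seq_len(cfg$nConfounds))
  }
  if (cfg$noiseSd > 0)
    X <- X + matrix(rnorm(length(X), sd = cfg$noiseSd), nrow(X), ncol(X))
  list(ts = ROITimeSeries(X, dt = cfg$dt, subjectId = subjectId,
                          group = group, protocol = cfg$protocol,
                          confounds = conf),
       active = active)
}

#' Generate one synthetic subject
#'
#' Draws one subject from the generative model (active modes chosen by the
#' cohort's occurrence probabilities, random amplitude and phase per
#' active mode, confound mixture, white noise).
#'
#' @param cfg a [syntheticConfig()].
#' @param group cohort label, `"A"` or `"B"`.
#' @param seed integer seed for this subject.
#' @param subjectId identifier stamped on the output.
#' @return An [ROITimeSeries-class]; the realized confound series are in
#'   its `confounds` slot and the active-mode set in
#'   `attr(, "activeModes")`.
#' @export
generateSubject <- function(cfg, group = c("A", "B"), seed = 1L,
                            subjectId = "subject") {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  group <- match.arg(group)
  patterns <- makeSpatialPatterns(cfg$nRoi, cfg$nModes, seed = cfg$seed)
  out <- withr::with_seed(as.integer(seed),
                          drawSubject(cfg, group, patterns, subjectId))
  ts <- out$ts
  attr(ts, "activeModes") <- out$active
  ts
}

#' Generate a full two-cohort collection with ground truth
#'
#' @param cfg a [syntheticConfig()].
#' @return A list with `subjects` (list of [ROITimeSeries-class], cohort A
#'   first) and `groundTruth` (spatial patterns, per-subject active-mode
#'   sets, the configured occurrence probabilities, and which modes are
#'   differential between the cohorts).
#' @examples
#' cohort <- generateCohort(syntheticConfig(nRoi = 12, nTimepoints = 60,
#'                                          nSubjectsPerGroup = 2, seed = 1))
#' length(cohort$subjects)
#' @export
generateCohort <- function(cfg) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  patterns <- makeSpatialPatterns(cfg$nRoi, cfg$nModes, seed = cfg$seed)
  subjects <- vector("list", 2L * cfg$nSubjectsPerGroup)
  active <- vector("list", 2L * cfg$nSubjectsPerGroup)
  ids <- character(2L * cfg$nSubjectsPerGroup)
  withr::with_seed(cfg$seed, {
    i <- 0L
    for (group in c("A", "B")) {
      for (s in seq_len(cfg$nSubjectsPerGroup)) {
        i <- i + 1L
        ids[i] <- sprintf("%s%03d", tolower(group), s)
        out <- drawSubject(cfg, group, patterns, ids[i])
        subjects[[i]] <- out$ts
        active[[i]] <- out$active
      }
    }
  })
  names(active) <- ids
  differential <- which(cfg$occurrenceProbA != cfg$occurrenceProbB)
  list(subjects = subjects,
       groundTruth = list(spatialPatterns = patterns,
                          activeModes = active,
                          occurrenceProbA = cfg$occurrenceProbA,
                          occurrenceProbB = cfg$occurrenceProbB,
                          differentialModes = differential,
                          config = cfg))
}
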