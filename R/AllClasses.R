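#' @import methods
#' @importFrom stats cov quantile rnorm runif sd var median setNames
NULL

# ---------------------------------------------------------------------------
# ROITimeSeries: one subject's parcellated BOLD-like recording
# ---------------------------------------------------------------------------

#' ROITimeSeries: one subject's ROI-by-time signal matrix
#'
#' Container for a single subject's parcellated time series: an
#' `Nroi x NT` real matrix, the sampling interval `dt` (seconds; the
#' temporal resolution of the acquisition protocol), a subject identifier,
#' a cohort label (`"A"` or `"B"`, e.g. healthy controls vs patients), a
#' protocol tag, and an optional `NT x q` matrix of nuisance regressors
#' (motion parameters, global signal, CompCor components and the like)
#' recorded alongside the scan.
#'
#' @slot data numeric matrix, ROIs in rows, time points in columns.
#' @slot dt sampling interval in seconds (> 0).
#' @slot subjectId character scalar.
#' @slot group cohort label, `"A"` or `"B"`.
#' @slot protocol acquisition protocol tag.
#' @slot confounds numeric matrix with `NT` rows and zero or more named
#'   columns of nuisance series.
#'
#' @seealso [ROITimeSeries()], [preprocessSubject()], [dmdSubject()]
#' @export
setClass("ROITimeSeries",
  representation(
    data      = "matrix",
    dt        = "numeric",
    subjectId = "character",
    group     = "character",
    protocol  = "character",
    confounds = "matrix"
  )
)

setValidity("ROITimeSeries", function(object) {
  msg <- character()
  if (!is.numeric(object@data))
    msg <- c(msg, "'data' must be a numeric matrix")
  if (anyNA(object@data))
    msg <- c(msg, "'data' must not contain missing values")
  if (length(object@dt) != 1L || !is.finite(object@dt) || object@dt <= 0)
    msg <- c(msg, "'dt' must be a single positive number")
  if (length(object@subjectId) != 1L)
    msg <- c(msg, "'subjectId' must be a single string")
  if (length(object@group) != 1L || !object@group %in% c("A", "B"))
    msg <- c(msg, "'group' must be \"A\" or \"B\"")
  if (nrow(object@confounds) > 0L &&
      nrow(object@confounds) != ncol(object@data))
    msg <- c(msg, "'confounds' must have one row per time point")
  if (length(msg)) msg else TRUE
})

#' Construct an ROITimeSeries
#'
#' @param data numeric matrix, ROIs in rows, time points in columns.
#' @param dt sampling interval in seconds.
#' @param subjectId subject identifier.
#' @param group cohort label, `"A"` or `"B"`.
#' @param protocol protocol tag (default `"default"`).
#' @param confounds optional `NT x q` matrix of nuisance series.
#' @return An [ROITimeSeries-class] object.
#' @examples
#' ts <- ROITimeSeries(matrix(rnorm(40), 4, 10), dt = 2, subjectId = "s1",
#'                     group = "A")
#' nRoi(ts)
#' @export
ROITimeSeries <- function(data, dt, subjectId = "subject", group = "A",
                          protocol = "default",
                          confounds = matrix(0, ncol(data), 0L)) {
  new("ROITimeSeries", data = as.matrix(data), dt = dt,
      subjectId = as.character(subjectId), group = as.character(group),
      protocol = as.character(protocol), confounds = as.matrix(confounds))
}

# ---------------------------------------------------------------------------
# DMDResult: one subject's dynamic mode decomposition
# ---------------------------------------------------------------------------

#' DMDResult: dynamic modes and eigenvalues of one subject
#'
#' Result of the one-stacked time-delay-coordinates DMD of a subject's
#' conditioned time series. `modes` holds the dynamic modes as columns
#' (complex, `2*Nroi` entries each, unit Euclidean norm, global phase fixed
#' so that the largest-magnitude entry is real and positive); `eigenvalues`
#' the matching discrete-time eigenvalues; `frequencies` the per-mode
#' frequencies in Hz on the principal branch.
#'
#' @slot modes complex matrix (`2*Nroi x K`).
#' @slot eigenvalues complex vector of length `K`.
#' @slot frequencies numeric vector of length `K`, Hz.
#' @slot subjectId,group,protocol provenance of the subject.
#' @slot dt sampling interval in seconds.
#' @slot nRoi number of ROIs in the original series.
#' @export
setClass("DMDResult",
  representation(
    modes       = "matrix",
    eigenvalues = "complex",
    frequencies = "numeric",
    subjectId   = "character",
    group       = "character",
    protocol    = "character",
    dt          = "numeric",
    nRoi        = "integer"
  )
)

setValidity("DMDResult", function(object) {
  msg <- character()
  k <- ncol(object@modes)
  if (length(object@eigenvalues) != k)
    msg <- c(msg, "one eigenvalue per mode column required")
  if (length(object@frequencies) != k)
    msg <- c(msg, "one frequency per mode column required")
  if (nrow(object@modes) != 2L * object@nRoi)
    msg <- c(msg, "'modes' must have 2*nRoi rows")
  nyq <- 1 / (2 * object@dt)
  if (k > 0 && any(abs(object@frequencies) > nyq + 1e-12))
    msg <- c(msg, "frequencies must lie within the Nyquist band")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# ModeSet: pooled dynamic modes from many subjects
# ---------------------------------------------------------------------------

#' ModeSet: pooled dynamic modes from a two-cohort study
#'
#' Pools dynamic modes across subjects for manifold analysis. Each row is
#' one mode. `halfModes` stores the first `Nroi` complex entries of each
#' mode (the second block of the delay-stacked mode duplicates the first
#' up to the one-step propagator, so only the first block is carried
#' forward); `features` are the real feature vectors (real parts then
#' imaginary parts, length `2*Nroi`); `info` records provenance
#' (subjectId, group, protocol, modeIndex, frequencyHz, eigRe, eigIm);
#' `embedding` holds 2-D coordinates once [embedModes()] has run.
#'
#' @slot halfModes complex matrix (`n x Nroi`), one mode per row.
#' @slot features numeric matrix (`n x 2*Nroi`).
#' @slot info data.frame with one row per mode.
#' @slot embedding numeric matrix (`n x 2`), or 0-row before embedding.
#' @slot nRoi number of ROIs.
#' @export
setClass("ModeSet",
  representation(
    halfModes = "matrix",
    features  = "matrix",
    info      = "data.frame",
    embedding = "matrix",
    nRoi      = "integer"
  )
)

setValidity("ModeSet", function(object) {
  msg <- character()
  n <- nrow(object@halfModes)
  if (nrow(object@features) != n || nrow(object@info) != n)
    msg <- c(msg, "'halfModes', 'features' and 'info' must agree in rows")
  if (ncol(object@features) != 2L * object@nRoi)
    msg <- c(msg, "'features' must have 2*nRoi columns")
  if (nrow(object@embedding) > 0L && nrow(object@embedding) != n)
    msg <- c(msg, "'embedding' must have one row per mode (or none)")
  if (nrow(object@embedding) > 0L && any(!is.finite(object@embedding)))
    msg <- c(msg, "embedding coordinates must be finite")
  req <- c("subjectId", "group", "protocol", "modeIndex", "frequencyHz",
           "eigRe", "eigIm")
  if (!all(req %in% names(object@info)))
    msg <- c(msg, paste("'info' must contain columns:",
                        paste(req, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# DensityModel: Gaussian KDE on the 2-D manifold
# ---------------------------------------------------------------------------

#' DensityModel: bivariate Gaussian kernel density estimate
#'
#' Gaussian KDE over 2-D manifold coordinates with the Scott bandwidth
#' rule: the bandwidth matrix is the sample covariance scaled by
#' `n^(-1/(d+4))` squared (`d = 2`), and the mixture is normalized to
#' integrate to one.
#'
#' @slot points numeric matrix (`n x 2`) of sample points.
#' @slot bandwidthFactor Scott factor `n^(-1/6)`.
#' @slot sampleCovariance 2 x 2 sample covariance of the points.
#' @slot bwInverse inverse of the bandwidth matrix (cached).
#' @slot normConst normalizing constant of one kernel (cached).
#' @export
setClass("DensityModel",
  representation(
    points           = "matrix",
    bandwidthFactor  = "numeric",
    sampleCovariance = "matrix",
    bwInverse        = "matrix",
    normConst        = "numeric"
  )
)

setValidity("DensityModel", function(object) {
  msg <- character()
  if (nrow(object@points) < 2L)
    msg <- c(msg, "at least two sample points are required")
  if (ncol(object@points) != 2L)
    msg <- c(msg, "'points' must be a 2-column matrix")
  ev <- eigen(object@sampleCovariance, symmetric = TRUE,
              only.values = TRUE)$values
  if (any(ev <= 0))
    msg <- c(msg, "sample covariance must be positive definite")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# RatioModel: fitted uLSIF density-ratio function
# ---------------------------------------------------------------------------

#' RatioModel: direct density-ratio estimate between two cohorts
#'
#' Least-squares importance fitting of the ratio
#' numerator-density / denominator-density as a Gaussian kernel expansion
#' centered on a subsample of numerator points. With mixing coefficient
#' `alpha = 0` this is uLSIF; predictions are clipped at zero.
#'
#' @slot centers numeric matrix (`m x 2`) of kernel centers.
#' @slot weights numeric vector of `m` kernel weights.
#' @slot sigma Gaussian kernel width.
#' @slot eta ridge regularization strength.
#' @slot alpha relative mixing coefficient (fixed at 0).
#' @slot cvScores data.frame of cross-validation scores over (sigma, eta).
#' @slot direction free-text label of the ratio direction.
#' @export
setClass("RatioModel",
  representation(
    centers   = "matrix",
    weights   = "numeric",
    sigma     = "numeric",
    eta       = "numeric",
    alpha     = "numeric",
    cvScores  = "data.frame",
    direction = "character"
  )
)

setValidity("RatioModel", function(object) {
  msg <- character()
  if (nrow(object@centers) > 100L)
    msg <- c(msg, "at most 100 kernel centers are used")
  if (length(object@weights) != nrow(object@centers))
    msg <- c(msg, "one weight per center required")
  if (object@sigma <= 0 || object@eta <= 0)
    msg <- c(msg, "'sigma' and 'eta' must be positive")
  if (object@alpha != 0)
    msg <- c(msg, "only alpha = 0 (uLSIF) is supported")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# show methods
# ---------------------------------------------------------------------------

setMethod("show", "ROITimeSeries", function(object) {
  cat("ROITimeSeries:", object@subjectId,
      sprintf("(group %s, protocol %s)\n", object@group, object@protocol))
  cat(sprintf("  %d ROIs x %d time points, dt = %g s, %d confound series\n",
              nrow(object@data), ncol(object@data), object@dt,
              ncol(object@confounds)))
})

setMethod("show", "DMDResult", function(object) {
  cat("DMDResult:", object@subjectId,
      sprintf("(group %s)\n", object@group))
  cat(sprintf("  %d dynamic modes over %d ROIs (delay-stacked length %d)\n",
              ncol(object@modes), object@nRoi, nrow(object@modes)))
  if (length(object@frequencies))
    cat(sprintf("  |frequency| range: %.4f .. %.4f Hz\n",
                min(abs(object@frequencies)), max(abs(object@frequencies))))
})

setMethod("show", "ModeSet", function(object) {
  cat(sprintf("ModeSet: %d pooled dynamic modes over %d ROIs\n",
              nrow(object@features), object@nRoi))
  tab <- table(object@info$group)
  cat("  modes per group:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat("  embedded:", if (nrow(object@embedding) > 0L) "yes" else "no", "\n")
})

setMethod("show", "DensityModel", function(object) {
  cat(sprintf("DensityModel: Gaussian KDE on %d points, Scott factor %.4f\n",
              nrow(object@points), object@bandwidthFactor))
})

setMethod("show", "RatioModel", function(object) {
  cat(sprintf(
    "RatioModel (%s): %d centers, sigma = %g, eta = %g, alpha = %g\n",
    object@direction, nrow(object@centers), object@sigma, object@eta,
    object@alpha))
})

# ---------------------------------------------------------------------------
# accessors
# ---------------------------------------------------------------------------

#' @describeIn ROITimeSeries-class the signal matrix.
#' @param object an object.
#' @export
setGeneric("tsData", function(object) standardGeneric("tsData"))
#' @export
setMethod("tsData", "ROITimeSeries", function(object) object@data)

#' Number of ROIs
#' @param object an [ROITimeSeries-class], [DMDResult-class] or
#'   [ModeSet-class].
#' @export
setGeneric("nRoi", function(object) standardGeneric("nRoi"))
#' @export
setMethod("nRoi", "ROITimeSeries", function(object) nrow(object@data))
#' @export
setMethod("nRoi", "DMDResult", function(object) object@nRoi)
#' @export
setMethod("nRoi", "ModeSet", function(object) object@nRoi)

#' Sampling interval in seconds
#' @param object an object with a temporal resolution.
#' @export
setGeneric("samplingInterval",
           function(object) standardGeneric("samplingInterval"))
#' @export
setMethod("samplingInterval", "ROITimeSeries", function(object) object@dt)
#' @export
setMethod("samplingInterval", "DMDResult", function(object) object@dt)

#' Subject identifier
#' @param object an object carrying subject provenance.
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))
#' @export
setMethod("subjectId", "ROITimeSeries", function(object) object@subjectId)
#' @export
setMethod("subjectId", "DMDResult", function(object) object@subjectId)

#' Cohort label
#' @param object an object carrying a cohort label.
#' @export
setGeneric("groupLabel", function(object) standardGeneric("groupLabel"))
#' @export
setMethod("groupLabel", "ROITimeSeries", function(object) object@group)
#' @export
setMethod("groupLabel", "DMDResult", function(object) object@group)

#' Dynamic modes, eigenvalues, frequencies
#' @param object a [DMDResult-class].
#' @export
setGeneric("dmdModes", function(object) standardGeneric("dmdModes"))
#' @export
setMethod("dmdModes", "DMDResult", function(object) object@modes)

#' @rdname dmdModes
#' @export
setGeneric("dmdEigenvalues", function(object) standardGeneric("dmdEigenvalues"))
#' @export
setMethod("dmdEigenvalues", "DMDResult", function(object) object@eigenvalues)

#' @rdname dmdModes
#' @export
setGeneric("dmdFrequencies", function(object) standardGeneric("dmdFrequencies"))
#' @export
setMethod("dmdFrequencies", "DMDResult", function(object) object@frequencies)

#' Mode feature matrix, provenance table, embedding coordinates
#' @param object a [ModeSet-class].
#' @export
setGeneric("modeFeatures", function(object) standardGeneric("modeFeatures"))
#' @export
setMethod("modeFeatures", "ModeSet", function(object) object@features)

#' @rdname modeFeatures
#' @export
setGeneric("modeInfo", function(object) standardGeneric("modeInfo"))
#' @export
setMethod("modeInfo", "ModeSet", function(object) object@info)

#' @rdname modeFeatures
#' @export
setGeneric("modeEmbedding", function(object) standardGeneric("modeEmbedding"))
#' @export
setMethod("modeEmbedding", "ModeSet", function(object) {
  if (nrow(object@embedding) == 0L)
    stop("ModeSet has not been embedded yet; run embedModes() first")
  object@embedding
})

#' @rdname modeFeatures
#' @export
setGeneric("halfModes", function(object) standardGeneric("halfModes"))
#' @export
setMethod("halfModes", "ModeSet", function(object) object@halfModes)

#' Number of pooled modes
#' @param x a [ModeSet-class].
#' @export
setMethod("length", "ModeSet", function(x) nrow(x@features))
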