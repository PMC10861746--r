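# Signal conditioning: detrend -> confound regression -> z-score.
# No band-pass filtering anywhere: mode frequencies are recovered from the
# eigenvalues downstream, so the full band is kept.

projectOut <- function(X, design) {
  # residualize rows of X against the column space of `design` (NT x p)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    keep <- qrd$pivot[seq_len(qrd$rank)]
    warning(sprintf("confound design is rank deficient; dropping %d column(s)",
                    ncol(design) - qrd$rank))
    qrd <- qr(design[, keep, drop = FALSE])
  }
  Q <- qr.Q(qrd)
  X - (X %*% Q) %*% t(Q)
}

#' Remove per-ROI linear trends
#'
#' Removes the least-squares linear trend (intercept and slope against the
#' time index) from every ROI row, eliminating long-term drifts.
#'
#' @param ts an [ROITimeSeries-class].
#' @return An [ROITimeSeries-class] with detrended rows (row means ~ 0).
#' @export
detrendSeries <- function(ts) {
  stopifnot(is(ts, "ROITimeSeries"))
  nt <- ncol(ts@data)
  if (nt < 2L) stop("invalid input: at least two time points required")
  design <- cbind(1, seq_len(nt))
  initialize(ts, data = projectOut(ts@data, design))
}

#' Regress nuisance series out of every ROI
#'
#' Replaces each ROI row by its ordinary-least-squares residual against an
#' intercept plus the confound columns (motion, global signal, CompCor and
#' the like). Residuals are exactly orthogonal to every confound column.
#' Rank-deficient confound matrices are handled by dropping dependent
#' columns with a warning.
#'
#' @param ts an [ROITimeSeries-class].
#' @param confounds `NT x q` numeric matrix; defaults to the confounds
#'   carried by `ts`. `q = 0` reduces to mean-centering.
#' @return An [ROITimeSeries-class] of residuals.
#' @export
regressConfounds <- function(ts, confounds = ts@confounds) {
  stopifnot(is(ts, "ROITimeSeries"))
  confounds <- as.matrix(confounds)
  nt <- ncol(ts@data)
  if (nrow(confounds) > 0L && nrow(confounds) != nt)
    stop("confound matrix must have one row per time point")
  design <- cbind(rep(1, nt), if (ncol(confounds)) confounds else NULL)
  initialize(ts, data = projectOut(ts@data, design))
}

#' Z-score every ROI row
#'
#' Centers each row and scales it to unit sample standard deviation,
#' putting subjects from different protocols on a common scale.
#'
#' @param ts an [ROITimeSeries-class]; rows must have nonzero variance.
#' @return An [ROITimeSeries-class] with rows of mean 0 and sd 1.
#' @export
zscoreSeries <- function(ts) {
  stopifnot(is(ts, "ROITimeSeries"))
  X <- ts@data
  mu <- rowMeans(X)
  Xc <- X - mu
  s <- sqrt(rowSums(Xc^2) / (ncol(X) - 1L))
  # rows that are constant, exactly or up to cancellation noise relative
  # to the matrix scale, cannot be z-scored
  bad <- which(s <= 1e-10 * max(abs(Xc), 1))
  if (length(bad))
    stop(sprintf("invalid input: zero-variance ROI row(s): %s",
                 paste(bad, collapse = ", ")))
  initialize(ts, data = Xc / s)
}

#' Condition one subject for DMD
#'
#' Applies, in order: optional discard of initial seconds (for real
#' acquisitions that include pre-equilibration frames), linear
#' detrending, confound regression (intercept always included), and
#' z-scoring. Band-pass filtering is deliberately not applied.
#'
#' @param ts an [ROITimeSeries-class].
#' @param confounds optional confound matrix overriding `ts@confounds`.
#' @param discardSeconds initial data to drop, in seconds (default 0; the
#'   synthetic generator produces steady-state series).
#' @return A conditioned [ROITimeSeries-class]: rows have mean 0, unit
#'   sample sd, and are orthogonal to the confounds.
#' @examples
#' cfg <- syntheticConfig(nRoi = 10, nTimepoints = 80,
#'                        nSubjectsPerGroup = 1, seed = 2)
#' ts <- generateSubject(cfg, "A", seed = 3)
#' pp <- preprocessSubject(ts)
#' range(rowMeans(tsData(pp)))
#' @export
preprocessSubject <- function(ts, confounds = NULL, discardSeconds = 0) {
  stopifnot(is(ts, "ROITimeSeries"))
  if (discardSeconds > 0) {
    drop <- floor(discardSeconds / ts@dt)
    if (drop >= ncol(ts@data) - 3L)
      stop("discardSeconds leaves too few time points")
    if (drop > 0L) {
      conf <- ts@confounds
      if (nrow(conf) > 0L) conf <- conf[-seq_len(drop), , drop = FALSE]
      ts <- initialize(ts, data = ts@data[, -seq_len(drop), drop = FALSE],
                       confounds = conf)
    }
  }
  if (is.null(confounds)) confounds <- ts@confounds
  confounds <- as.matrix(confounds)
  if (ncol(confounds) > 0L) {
    # detrend the confound series with the same projection as the data;
    # otherwise the confounds' own linear-trend component survives the
    # regression and leaks a global low-frequency artifact into every ROI
    nt <- ncol(ts@data)
    design <- cbind(1, seq_len(nt))
    Q <- qr.Q(qr(design))
    confounds <- confounds - Q %*% crossprod(Q, confounds)
  }
  zscoreSeries(regressConfounds(detrendSeries(ts), confounds))
}
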