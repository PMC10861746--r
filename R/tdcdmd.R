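# One-stacked time-delay-coordinates DMD.
#
# Snapshots x_k are augmented with their one-step successors,
#   X1aug[, k] = [x_k; x_{k+1}],  X2aug[, k] = [x_{k+1}; x_{k+2}],
# and the exact DMD of the pair (X1aug, X2aug) yields modes (eigenvectors
# of the best-fit linear propagator A with X2aug ~ A X1aug) and
# discrete-time eigenvalues. The single stacking lets a real standing wave
# (rank-2 dynamics) be resolved even when its spatial pattern alone is
# rank-1 in the snapshot matrix.

#' Build one-stacked delay matrices
#'
#' @param ts an [ROITimeSeries-class] with at least 4 time points.
#' @return A list with `x1aug` and `x2aug` (`2*Nroi x (NT-2)` each):
#'   columns of `x1aug` are `[x_k; x_{k+1}]` for `k = 1..NT-2`, columns of
#'   `x2aug` the same stack advanced by one step.
#' @examples
#' ts <- ROITimeSeries(matrix(1:4, 1), dt = 1, subjectId = "toy", group = "A")
#' buildDelayMatrices(ts)
#' @export
buildDelayMatrices <- function(ts) {
  stopifnot(is(ts, "ROITimeSeries"))
  X <- ts@data
  nt <- ncol(X)
  if (nt < 4L)
    stop("invalid input: at least 4 time points are needed for one-stacked ",
         "delay matrices")
  list(
    x1aug = rbind(X[, 1:(nt - 2L), drop = FALSE],
                  X[, 2:(nt - 1L), drop = FALSE]),
    x2aug = rbind(X[, 2:(nt - 1L), drop = FALSE],
                  X[, 3:nt, drop = FALSE])
  )
}

#' Exact DMD of a delay-matrix pair
#'
#' Computes the truncated SVD `x1aug = U S V'`, the reduced propagator
#' `Atilde = U' x2aug V S^-1`, its eigendecomposition `Atilde W = W L`,
#' and the exact dynamic modes `Phi = x2aug V S^-1 W`. Columns of `Phi`
#' are eigenvectors of the full propagator `A = x2aug pinv(x1aug)` with
#' eigenvalues `L`.
#'
#' @param dm list with `x1aug`, `x2aug` (from [buildDelayMatrices()]).
#' @param rankTol relative singular-value cutoff: components with
#'   `s < rankTol * s[1]` are truncated (default `1e-10`), which also
#'   regularizes the pseudo-inverse.
#' @return A list with `svd` (list `u`, `s`, `v`, `rankKept`),
#'   `eigenvalues` (complex, length K) and `modes` (complex
#'   `2*Nroi x K`, unnormalized).
#' @export
exactDMD <- function(dm, rankTol = 1e-10) {
  x1 <- dm$x1aug
  x2 <- dm$x2aug
  sv <- svd(x1)
  if (sv$d[1] <= .Machine$double.xmin) {
    warning("all singular values are numerically zero; returning empty result")
    return(list(svd = list(u = sv$u[, 0, drop = FALSE], s = numeric(0),
                           v = sv$v[, 0, drop = FALSE], rankKept = 0L),
                eigenvalues = complex(0),
                modes = matrix(complex(0), nrow(x1), 0L)))
  }
  keep <- which(sv$d >= rankTol * sv$d[1])
  U <- sv$u[, keep, drop = FALSE]
  V <- sv$v[, keep, drop = FALSE]
  s <- sv$d[keep]
  VSinv <- V %*% diag(1 / s, length(s))
  x2VSinv <- x2 %*% VSinv
  Atilde <- crossprod(U, x2VSinv)
  eg <- eigen(Atilde)
  modes <- x2VSinv %*% eg$vectors
  list(svd = list(u = U, s = s, v = V, rankKept = length(s)),
       eigenvalues = as.complex(eg$values),
       modes = matrix(as.complex(modes), nrow(x1), length(s)))
}

#' Frequency of a discrete-time eigenvalue
#'
#' Maps an eigenvalue of the one-step propagator to a frequency in Hz on
#' the principal branch: `f = Im(log(lambda)) / (2 * pi * dt)`, so
#' `f` lies in `(-1/(2 dt), 1/(2 dt)]`.
#'
#' @param lambda complex eigenvalue(s); must be nonzero.
#' @param dt sampling interval in seconds.
#' @return Frequency in Hz (vectorized over `lambda`).
#' @examples
#' eigenvalueFrequency(exp(1i * pi / 2), dt = 2)  # 0.0625 Hz
#' @export
eigenvalueFrequency <- function(lambda, dt) {
  lambda <- as.complex(lambda)
  if (any(Mod(lambda) == 0))
    stop("undefined frequency: eigenvalue is zero")
  Im(log(lambda)) / (2 * pi * dt)
}

# Fix the arbitrary global phase of each mode column: rotate so the entry
# with the largest magnitude (first such index on ties) is real positive.
fixModePhase <- function(modes) {
  if (ncol(modes) == 0L) return(modes)
  for (j in seq_len(ncol(modes))) {
    i <- which.max(Mod(modes[, j]))
    z <- modes[i, j]
    if (Mod(z) > 0) modes[, j] <- modes[, j] * Conj(z) / Mod(z)
  }
  modes
}

#' Dynamic mode decomposition of one subject
#'
#' Runs one-stacked delay embedding and exact DMD on a conditioned
#' subject, normalizes every retained mode to unit Euclidean norm over its
#' `2*Nroi` entries, fixes each mode's global phase (largest-magnitude
#' entry real positive, so conjugate pairs are elementwise conjugates),
#' and computes per-mode frequencies. Eigenvalues of numerically zero
#' modulus (below `1e-12`) are dropped with their modes since they carry
#' no dynamics and have no defined frequency.
#'
#' @param ts a preprocessed [ROITimeSeries-class].
#' @param rankTol relative SVD truncation tolerance (default `1e-10`).
#' @return A [DMDResult-class].
#' @examples
#' cfg <- syntheticConfig(nRoi = 10, nTimepoints = 80,
#'                        nSubjectsPerGroup = 1, seed = 2)
#' res <- dmdSubject(preprocessSubject(generateSubject(cfg, "A", seed = 3)))
#' res
#' @export
dmdSubject <- function(ts, rankTol = 1e-10) {
  stopifnot(is(ts, "ROITimeSeries"))
  dm <- buildDelayMatrices(ts)
  fit <- exactDMD(dm, rankTol = rankTol)
  lam <- fit$eigenvalues
  keep <- which(Mod(lam) > 1e-12)
  lam <- lam[keep]
  modes <- fit$modes[, keep, drop = FALSE]
  nrm <- sqrt(colSums(Mod(modes)^2))
  nz <- nrm > 0
  lam <- lam[nz]
  modes <- modes[, nz, drop = FALSE]
  modes <- sweep(modes, 2L, nrm[nz], "/")
  modes <- fixModePhase(modes)
  new("DMDResult", modes = modes, eigenvalues = lam,
      frequencies = if (length(lam)) eigenvalueFrequency(lam, ts@dt)
                    else numeric(0),
      subjectId = ts@subjectId, group = ts@group, protocol = ts@protocol,
      dt = ts@dt, nRoi = nrow(ts@data))
}

#' Decompose every subject of a cohort
#'
#' @param subjects list of conditioned [ROITimeSeries-class] objects.
#' @param rankTol relative SVD truncation tolerance.
#' @return A list of [DMDResult-class] objects.
#' @export
dmdCohort <- function(subjects, rankTol = 1e-10) {
  lapply(subjects, dmdSubject, rankTol = rankTol)
}
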