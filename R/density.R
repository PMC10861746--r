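# Bivariate Gaussian KDE with Scott's rule, and evaluation grids.

#' Fit a Gaussian kernel density estimate
#'
#' Normalized Gaussian KDE on 2-D points with Scott's rule: bandwidth
#' matrix = sample covariance times `n^(-1/6)` squared. Densities
#' integrate to one, so they are comparable across cohorts of different
#' sizes.
#'
#' @param points numeric matrix (`n x 2`), `n >= 2`, nondegenerate.
#' @return A [DensityModel-class].
#' @export
kdeFit <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2L)
    stop("at least two points are required to fit a KDE")
  if (ncol(points) != 2L) stop("points must be a 2-column matrix")
  n <- nrow(points)
  S <- cov(points)
  if (n == 2L) {
    # a two-point sample covariance is always rank one; fall back to a
    # diagonal bandwidth with a floored variance per axis
    v <- diag(S)
    if (max(v) <= 0) stop("the two points must be distinct")
    S <- diag(pmax(v, 1e-6 * max(v)))
  }
  fac <- n^(-1 / 6)
  bw <- S * fac^2
  ch <- tryCatch(chol(bw), error = function(e) NULL)
  if (is.null(ch))
    stop("degenerate (collinear) points: add a small jitter before fitting")
  bwInv <- chol2inv(ch)
  normConst <- 1 / (2 * pi * sqrt(det(bw)))
  new("DensityModel", points = points, bandwidthFactor = fac,
      sampleCovariance = S, bwInverse = bwInv, normConst = normConst)
}

#' Evaluate a fitted KDE
#'
#' @param model a [DensityModel-class].
#' @param queries numeric matrix (`k x 2`) of evaluation points.
#' @return Numeric vector of `k` nonnegative density values.
#' @export
kdeEvaluate <- function(model, queries) {
  stopifnot(is(model, "DensityModel"))
  queries <- as.matrix(queries)
  if (ncol(queries) != 2L) stop("queries must be a 2-column matrix")
  # Mahalanobis cross-distances under the bandwidth metric
  A <- model@bwInverse
  X <- model@points
  xa <- X %*% A
  qa <- queries %*% A
  qn <- rowSums(qa * queries)
  xn <- rowSums(xa * X)
  d2 <- outer(qn, xn, "+") - 2 * tcrossprod(qa, X)
  d2[d2 < 0] <- 0
  as.numeric(model@normConst * rowMeans(exp(-0.5 * d2)))
}

#' Build a regular evaluation grid
#'
#' Axis-aligned bounding box of the points, expanded by `marginFrac` per
#' side, discretized into `resolution x resolution` nodes. Degenerate
#' extents are widened to a documented floor of `1e-6`.
#'
#' @param points numeric matrix (`n x 2`), `n >= 2`.
#' @param resolution nodes per axis (default 100, minimum 50).
#' @param marginFrac margin per side as a fraction of the extent
#'   (default 0.05).
#' @return A list of class `"GridSpec"` with `x`, `y` (node coordinates)
#'   and `resolution`.
#' @export
makeGrid <- function(points, resolution = 100L, marginFrac = 0.05) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) stop("at least two points are required")
  resolution <- max(50L, as.integer(resolution))
  rng <- apply(points[, 1:2, drop = FALSE], 2L, range)
  span <- pmax(rng[2, ] - rng[1, ], 1e-6)
  lo <- rng[1, ] - marginFrac * span
  hi <- rng[2, ] + marginFrac * span
  structure(list(x = seq(lo[1], hi[1], length.out = resolution),
                 y = seq(lo[2], hi[2], length.out = resolution),
                 resolution = resolution),
            class = "GridSpec")
}

#' All nodes of a grid as a two-column matrix
#'
#' Nodes are ordered x-fastest (column-major in the `x` by `y` field
#' matrix).
#'
#' @param grid a `"GridSpec"` from [makeGrid()].
#' @return Numeric matrix (`resolution^2 x 2`).
#' @export
gridNodes <- function(grid) {
  cbind(rep(grid$x, times = length(grid$y)),
        rep(grid$y, each = length(grid$x)))
}
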