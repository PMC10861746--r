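# Direct density-ratio estimation by unconstrained least-squares
# importance fitting (uLSIF; the alpha = 0 case of the relative variant).
#
# The ratio r(x) = p_num(x) / p_den(x) is modelled as a Gaussian kernel
# expansion r_theta(x) = sum_l theta_l k(x, c_l) with centers c_l drawn
# from the numerator sample. Minimizing the squared error
# E_den[(r_theta - r)^2] up to a constant gives the quadratic objective
#   J(theta) = 1/2 theta' H theta - h' theta,
#   H_{ll'} = E_den[k(x,c_l) k(x,c_l')],  h_l = E_num[k(x,c_l)],
# solved in closed form with a ridge term: theta = (H + eta I)^{-1} h.
# (sigma, eta) are chosen by k-fold cross-validation of J; predictions
# are clipped at zero.

ulsifTheta <- function(Knum, Kden, eta) {
  H <- crossprod(Kden) / nrow(Kden)
  h <- colMeans(Knum)
  solve(H + diag(eta, ncol(Kden)), h)
}

ulsifJ <- function(theta, Knum, Kden) {
  H <- crossprod(Kden) / nrow(Kden)
  h <- colMeans(Knum)
  0.5 * sum(theta * (H %*% theta)) - sum(h * theta)
}

#' Fit a density ratio by uLSIF
#'
#' Estimates `p_num / p_den` directly from two 2-D samples, which is more
#' accurate than fitting two KDEs and dividing. Kernel centers are
#' `min(nCenters, n_num)` numerator points drawn uniformly without
#' replacement (seeded). For every (sigma, eta) pair on the grids the
#' ridge-regularized least-squares weights are computed in closed form;
#' the pair minimizing the k-fold cross-validated squared-error criterion
#' J is selected (ties: first pair in grid order, sigma varying slowest).
#'
#' @param numerator,denominator numeric matrices (`n x 2`), at least 50
#'   rows each.
#' @param sigmaGrid Gaussian kernel widths to try.
#' @param etaGrid ridge penalties to try (all > 0).
#' @param seed integer seed (center subsampling and CV folds).
#' @param nCenters maximum number of kernel centers (default 100).
#' @param nFolds cross-validation folds (default 5).
#' @param direction free-text label stored on the model.
#' @return A [RatioModel-class].
#' @examples
#' set.seed(1)
#' a <- matrix(rnorm(400), ncol = 2)
#' b <- matrix(rnorm(400), ncol = 2)
#' m <- ulsifFit(a, b, sigmaGrid = c(0.5, 1), etaGrid = c(0.1, 0.01),
#'               seed = 1)
#' mean(ratioPredict(m, b))  # ~ 1 for identical distributions
#' @export
ulsifFit <- function(numerator, denominator,
                     sigmaGrid = c(1.2, 1.0, 0.8),
                     etaGrid = seq(0.10, 0.01, by = -0.01),
                     seed = 0L, nCenters = 100L, nFolds = 5L,
                     direction = "num/den") {
  numerator <- as.matrix(numerator)
  denominator <- as.matrix(denominator)
  if (nrow(numerator) < 50L || nrow(denominator) < 50L)
    stop("both samples need at least 50 points")
  if (length(sigmaGrid) == 0L || length(etaGrid) == 0L)
    stop("sigma and eta grids must be nonempty")
  if (any(etaGrid <= 0)) stop("all ridge penalties must be positive")
  nn <- nrow(numerator)
  nd <- nrow(denominator)
  m <- min(as.integer(nCenters), nn, 100L)
  res <- withr::with_seed(as.integer(seed), {
    centers <- numerator[sample.int(nn, m), , drop = FALSE]
    foldNum <- sample(rep_len(seq_len(nFolds), nn))
    foldDen <- sample(rep_len(seq_len(nFolds), nd))
    list(centers = centers, foldNum = foldNum, foldDen = foldDen)
  })
  centers <- res$centers
  cv <- expand.grid(eta = etaGrid, sigma = sigmaGrid,
                    KEEP.OUT.ATTRS = FALSE)[, c("sigma", "eta")]
  cv$score <- NA_real_
  best <- NULL
  for (sigma in sigmaGrid) {
    Knum <- gaussKernel(numerator, centers, sigma)
    Kden <- gaussKernel(denominator, centers, sigma)
    for (eta in etaGrid) {
      js <- vapply(seq_len(nFolds), function(f) {
        trN <- res$foldNum != f; trD <- res$foldDen != f
        th <- ulsifTheta(Knum[trN, , drop = FALSE],
                         Kden[trD, , drop = FALSE], eta)
        ulsifJ(th, Knum[!trN, , drop = FALSE], Kden[!trD, , drop = FALSE])
      }, numeric(1))
      score <- mean(js)
      cv$score[cv$sigma == sigma & cv$eta == eta] <- score
      if (is.null(best) || score < best$score)
        best <- list(sigma = sigma, eta = eta, score = score,
                     Knum = Knum, Kden = Kden)
    }
  }
  theta <- ulsifTheta(best$Knum, best$Kden, best$eta)
  new("RatioModel", centers = centers, weights = as.numeric(theta),
      sigma = best$sigma, eta = best$eta, alpha = 0,
      cvScores = cv, direction = direction)
}

# Single-(sigma, eta) fit without model selection; used inside
# permutations where the parameters are held fixed.
ulsifFitFixed <- function(numerator, denominator, sigma, eta, seed = 0L,
                          nCenters = 100L, direction = "num/den") {
  numerator <- as.matrix(numerator)
  denominator <- as.matrix(denominator)
  nn <- nrow(numerator)
  m <- min(as.integer(nCenters), nn, 100L)
  centers <- withr::with_seed(as.integer(seed),
                              numerator[sample.int(nn, m), , drop = FALSE])
  Knum <- gaussKernel(numerator, centers, sigma)
  Kden <- gaussKernel(denominator, centers, sigma)
  theta <- ulsifTheta(Knum, Kden, eta)
  new("RatioModel", centers = centers, weights = as.numeric(theta),
      sigma = sigma, eta = eta, alpha = 0,
      cvScores = data.frame(sigma = sigma, eta = eta, score = NA_real_),
      direction = direction)
}

#' Evaluate a fitted density ratio
#'
#' @param model a [RatioModel-class].
#' @param x numeric matrix (`k x 2`) of query points.
#' @return Numeric vector of `k` ratio values, clipped at zero.
#' @export
ratioPredict <- function(model, x) {
  stopifnot(is(model, "RatioModel"))
  x <- as.matrix(x)
  pmax(0, as.numeric(gaussKernel(x, model@centers, model@sigma) %*%
                       model@weights))
}

#' Evaluate a density ratio on a grid
#'
#' @param model a [RatioModel-class].
#' @param grid a `"GridSpec"` from [makeGrid()].
#' @return A list of class `"DensityField"` with the grid and a
#'   `resolution x resolution` matrix `values` (x along rows).
#' @export
ratioField <- function(model, grid) {
  vals <- ratioPredict(model, gridNodes(grid))
  structure(list(grid = grid,
                 values = matrix(vals, grid$resolution, grid$resolution)),
            class = "DensityField")
}

#' Evaluate a KDE on a grid
#'
#' @param model a [DensityModel-class].
#' @param grid a `"GridSpec"`.
#' @return A `"DensityField"` as in [ratioField()].
#' @export
densityFieldOf <- function(model, grid) {
  vals <- kdeEvaluate(model, gridNodes(grid))
  structure(list(grid = grid,
                 values = matrix(vals, grid$resolution, grid$resolution)),
            class = "DensityField")
}

#' Adapt the kernel-width grid to an embedding's scale
#'
#' The reference kernel widths (1.2, 1.0, 0.8) presume embeddings at the
#' coordinate scale of very large mode collections. For smaller
#' collections the grid is rescaled by the median 10th-nearest-neighbour
#' distance of the pooled embedding so that kernels always span a
#' comparable number of neighbours; above `largeN` points the reference
#' grid is returned unchanged.
#'
#' @param coords embedding coordinates (`n x 2`).
#' @param baseGrid reference widths (default `c(1.2, 1.0, 0.8)`).
#' @param largeN sample size above which the reference grid is kept
#'   (default 20000).
#' @return Numeric vector of kernel widths.
#' @export
scaledSigmaGrid <- function(coords, baseGrid = c(1.2, 1.0, 0.8),
                            largeN = 20000L) {
  n <- nrow(coords)
  if (n > largeN) return(baseGrid)
  s <- medianKnnDistance(as.matrix(coords), k = 10L)
  baseGrid * s
}
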