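# internal helpers

# Deterministic per-stage seed derived from a master seed and a stage name.
# Kept strictly below 2^31 so it is always a valid R integer seed.
stageSeed <- function(masterSeed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(masterSeed) * 1000003 + h * 2654435) %% 2147483629)
}

# Squared Euclidean distances between rows of a (n x d) and rows of b (m x d).
crossDist2 <- function(a, b) {
  an <- rowSums(a * a)
  bn <- rowSums(b * b)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

# Gaussian kernel matrix exp(-||x - c||^2 / (2 sigma^2)).
gaussKernel <- function(x, centers, sigma) {
  exp(-crossDist2(x, centers) / (2 * sigma^2))
}

# Median distance to the k-th nearest neighbour; a robust local length
# scale used to adapt kernel-width grids to the spread of an embedding.
# Evaluated on a deterministic subsample of at most 2000 query points so
# memory stays linear in n.
medianKnnDistance <- function(points, k = 10L) {
  n <- nrow(points)
  k <- min(k, n - 1L)
  idx <- unique(round(seq(1L, n, length.out = min(n, 2000L))))
  d2 <- crossDist2(points[idx, , drop = FALSE], points)
  kd <- apply(d2, 1L, function(r) sqrt(sort(r, partial = k + 1L)[k + 1L]))
  stats::median(kd)
}

stopifnotScalarCount <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 1 || x != round(x))
    stop(sprintf("'%s' must be a single positive integer", name))
  invisible(as.integer(x))
}
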