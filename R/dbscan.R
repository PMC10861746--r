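# DBSCAN with documented deterministic semantics.
#
# Core point: at least minSamples points (self included) within radius
# eps. Clusters are grown from core points scanned in index order
# (lowest-index core point seeds first); border points join the cluster
# that reaches them first, i.e. the earliest-seeded cluster among their
# core neighbours. Everything else is noise.

#' DBSCAN cluster labels
#'
#' @param points numeric matrix (`n x d`).
#' @param eps neighbourhood radius (> 0).
#' @param minSamples minimum neighbourhood size (self included) for a
#'   core point.
#' @return Integer vector of length `n`: cluster ids `1, 2, ...` in seed
#'   order, `0` for noise.
#' @examples
#' pts <- rbind(matrix(rnorm(60, 0, 0.05), ncol = 2),
#'              matrix(rnorm(60, 10, 0.05), ncol = 2))
#' table(dbscanLabels(pts, eps = 1, minSamples = 10))
#' @export
dbscanLabels <- function(points, eps, minSamples) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n == 0L) return(integer(0))
  stopifnot(eps > 0, minSamples >= 1)
  d2 <- crossDist2(points, points)
  within <- d2 <= eps^2
  degree <- rowSums(within)
  core <- degree >= minSamples
  labels <- integer(n)          # 0 = noise / unassigned
  clusterId <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    clusterId <- clusterId + 1L
    labels[i] <- clusterId
    queue <- i
    while (length(queue)) {
      p <- queue[[1]]
      queue <- queue[-1]
      nb <- which(within[p, ])
      for (q in nb) {
        if (labels[q] == 0L) {
          labels[q] <- clusterId
          if (core[q]) queue <- c(queue, q)
        }
      }
    }
  }
  labels
}
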