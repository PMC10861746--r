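mkField <- function(values) {
  grid <- makeGrid(rbind(c(0, 0), c(1, 1)),
                   resolution = max(50L, nrow(values)))
  structure(list(grid = grid, values = values), class = "DensityField")
}

test_that("maxPeak returns the supremum over grid nodes", {
  expect_identical(maxPeak(mkField(matrix(0, 50, 50))), 0)
  spike <- matrix(0, 50, 50); spike[17, 33] <- 7
  expect_identical(maxPeak(mkField(spike)), 7)
  # refining a grid can only raise the supremum over its nodes
  withr::with_seed(1, pts <- matrix(rnorm(400), ncol = 2))
  fit <- ulsifFit(pts, pts, sigmaGrid = 1, etaGrid = 0.1, seed = 1)
  coarse <- maxPeak(ratioField(fit, makeGrid(pts, resolution = 50)))
  fine <- maxPeak(ratioField(fit, makeGrid(pts, resolution = 150)))
  expect_gte(fine, coarse - 1e-12)
})

test_that("the permutation threshold follows the linear-interpolation percentile rule", {
  withr::with_seed(2, coords <- matrix(rnorm(240), ncol = 2))
  labels <- rep(c("A", "B"), each = 60)
  grid <- makeGrid(coords, resolution = 50)
  p1 <- permutationNull(coords, labels, "A", sigma = 1, eta = 0.05,
                        grid = grid, nPerm = 1, seed = 3)
  expect_identical(p1$threshold, p1$nullMaxPeaks[1])
  expect_equal(unname(quantile(1:100, 0.95, type = 7)), 95.05,
               tolerance = 1e-12)
  p <- permutationNull(coords, labels, "A", sigma = 1, eta = 0.05,
                       grid = grid, nPerm = 20, seed = 3)
  expect_identical(p$threshold,
                   as.numeric(quantile(p$nullMaxPeaks, 0.95, type = 7)))
  expect_error(permutationNull(coords, rep("A", 120), "A", 1, 0.05, grid,
                               nPerm = 2, seed = 1), "both cohort")
})

test_that("the null is invariant to swapping equally sized cohorts", {
  withr::with_seed(4, coords <- matrix(rnorm(300), ncol = 2))
  labels <- rep(c("A", "B"), 75)
  swapped <- ifelse(labels == "A", "B", "A")
  grid <- makeGrid(coords, resolution = 50)
  pa <- permutationNull(coords, labels, "A", sigma = 1, eta = 0.05,
                        grid = grid, nPerm = 10, seed = 5)
  pb <- permutationNull(coords, swapped, "B", sigma = 1, eta = 0.05,
                        grid = grid, nPerm = 10, seed = 5)
  expect_equal(pa$nullMaxPeaks, pb$nullMaxPeaks, tolerance = 1e-12)
})

test_that("block-level permutation moves all of a subject's modes together", {
  withr::with_seed(11, coords <- matrix(rnorm(240), ncol = 2))
  subjects <- rep(sprintf("s%02d", 1:12), each = 10)
  labels <- rep(rep(c("A", "B"), 6), each = 10)
  grid <- makeGrid(coords, resolution = 50)
  p <- permutationNull(coords, labels, "A", sigma = 1, eta = 0.05,
                       grid = grid, nPerm = 5, seed = 6, blocks = subjects)
  expect_length(p$nullMaxPeaks, 5L)
  expect_true(all(is.finite(p$nullMaxPeaks)))
  # labels varying within a block are rejected
  badLabels <- labels; badLabels[1] <- "B"
  expect_error(permutationNull(coords, badLabels, "A", 1, 0.05, grid,
                               nPerm = 2, seed = 1, blocks = subjects),
               "constant within")
  # block and mode nulls generally differ: blocked shuffles are coarser
  pm <- permutationNull(coords, labels, "A", sigma = 1, eta = 0.05,
                        grid = grid, nPerm = 5, seed = 6)
  expect_false(isTRUE(all.equal(p$nullMaxPeaks, pm$nullMaxPeaks)))
})

test_that("significant-mode selection respects the threshold and is monotone", {
  withr::with_seed(6, feats <- matrix(rnorm(120 * 4), 120))
  ms <- new("ModeSet",
            halfModes = matrix(complex(real = feats[, 1:2],
                                       imaginary = feats[, 3:4]), 120, 2),
            features = feats,
            info = data.frame(subjectId = "s", group = rep(c("A", "B"), 60),
                              protocol = "p", modeIndex = 1:120,
                              frequencyHz = 0.05, eigRe = 1, eigIm = 0),
            embedding = matrix(rnorm(240), 120, 2), nRoi = 2L)
  m <- new("RatioModel", centers = matrix(c(0, 0), 1, 2), weights = 2,
           sigma = 5, eta = 0.01, alpha = 0, cvScores = data.frame(),
           direction = "t")
  r <- ratioPredict(m, modeEmbedding(ms))
  expect_true(all(r > 0))
  expect_identical(significantModes(ms, m, threshold = 0), seq_len(120))
  expect_identical(significantModes(ms, m, threshold = max(r) + 1),
                   integer(0))
  t1 <- significantModes(ms, m, threshold = median(r))
  t2 <- significantModes(ms, m, threshold = quantile(r, 0.9))
  expect_true(all(t2 %in% t1))
})

test_that("DBSCAN handles the canonical disc scenarios", {
  withr::with_seed(7, {
    disc <- cbind(runif(150, -0.07, 0.07), runif(150, -0.07, 0.07))
    far <- disc + 10
    scatter <- matrix(runif(100, 0, 50), ncol = 2)
  })
  l1 <- dbscanLabels(disc, eps = 1, minSamples = 100)
  expect_identical(unique(l1), 1L)
  l2 <- dbscanLabels(rbind(disc, far), eps = 1, minSamples = 100)
  expect_identical(sort(unique(l2)), c(1L, 2L))
  expect_identical(unique(l2[1:150]), 1L)
  expect_identical(unique(l2[151:300]), 2L)
  l3 <- dbscanLabels(scatter, eps = 1, minSamples = 100)
  expect_identical(unique(l3), 0L)
})

test_that("DBSCAN matches the brute-force eps-graph reference on random sets", {
  withr::with_seed(8, {
    for (rep in 1:12) {
      n <- sample(30:120, 1)
      pts <- matrix(runif(2 * n, 0, 10), ncol = 2)
      eps <- runif(1, 0.3, 2)
      minS <- sample(3:12, 1)
      ours <- dbscanLabels(pts, eps, minS)
      ref <- bruteDbscan(pts, eps, minS)
      expect_true(samePartition(ours, ref))
    }
  })
})

test_that("cluster construction drops noise, orders by size, and tracks direction", {
  withr::with_seed(9, {
    blobA <- matrix(rnorm(600, sd = 0.3), ncol = 2)
    blobB <- cbind(rnorm(80, sd = 0.3) + 8, rnorm(80, sd = 0.3))
    lone <- matrix(c(30, 30, 31, 31), 2, byrow = TRUE)
  })
  coords <- rbind(blobA, blobB, lone)
  n <- nrow(coords)
  ms <- new("ModeSet",
            halfModes = matrix(complex(real = 1), n, 1),
            features = matrix(0, n, 2),
            info = data.frame(subjectId = "s", group = "A", protocol = "p",
                              modeIndex = seq_len(n), frequencyHz = 0,
                              eigRe = 1, eigIm = 0),
            embedding = coords, nRoi = 1L)
  expect_identical(buildClusters(ms, integer(0), eps = 1, minSamples = 5),
                   list())
  cl <- buildClusters(ms, seq_len(n), eps = 1, minSamples = 10,
                      direction = "AoverB")
  expect_identical(length(cl), 2L)
  expect_gt(cl[[1]]$size, cl[[2]]$size)
  expect_gte(cl[[1]]$size, 300 * 0.9)
  expect_identical(cl[[1]]$direction, "AoverB")
  # the two lone points are noise and appear in no cluster
  members <- unlist(lapply(cl, `[[`, "members"))
  expect_false(any((n - 1):n %in% members))
})
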