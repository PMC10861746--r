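test_that("mode features stack real then imaginary parts of the first ROI block", {
  d <- manualDMDResult(c(1 + 2i, 3 - 1i))
  f <- modeToFeature(d, 1)
  half <- d@modes[1:2, 1]
  expect_equal(f, c(Re(half), Im(half)), tolerance = 1e-12)
  # the un-normalized entries keep the stated proportions 1,3 / 2,-1
  expect_equal(f[1:2] / f[1], c(1, 3), tolerance = 1e-12)
  expect_equal(f[3:4] / f[1], c(2, -1), tolerance = 1e-12)
  expect_error(modeToFeature(d, 2), "out of range")

  # purely real mode: imaginary half is all zero
  dr <- manualDMDResult(c(2, 1), eigenvalue = 0.95 + 0i)
  expect_equal(modeToFeature(dr, 1)[3:4], c(0, 0), tolerance = 1e-12)
})

test_that("feature construction is an isometry and mirrors conjugate modes", {
  cfg <- tinyConfig(noiseSd = 0.05)
  res <- dmdSubject(preprocessSubject(generateSubject(cfg, "A", seed = 3)))
  ms <- poolModes(list(res))
  feats <- modeFeatures(ms)
  for (j in seq_len(ncol(dmdModes(res)))) {
    half <- dmdModes(res)[1:nRoi(res), j]
    expect_equal(sqrt(sum(feats[j, ]^2)), sqrt(sum(Mod(half)^2)),
                 tolerance = 1e-12)
  }
  lam <- dmdEigenvalues(res)
  j <- which(Im(lam) > 1e-6)[1]
  k <- which.min(Mod(lam - Conj(lam[j])))
  nroi <- nRoi(res)
  expect_equal(feats[k, 1:nroi], feats[j, 1:nroi], tolerance = 1e-6)
  expect_equal(feats[k, (nroi + 1):(2 * nroi)],
               -feats[j, (nroi + 1):(2 * nroi)], tolerance = 1e-6)
})

test_that("pooling preserves provenance and counts", {
  cfg <- tinyConfig(nSubjectsPerGroup = 2L)
  co <- generateCohort(cfg)
  dmds <- dmdCohort(lapply(co$subjects, preprocessSubject))
  ms <- poolModes(dmds)
  expect_identical(length(ms), sum(vapply(dmds, function(d)
    ncol(dmdModes(d)), integer(1))))
  info <- modeInfo(ms)
  expect_identical(sort(unique(info$subjectId)),
                   sort(vapply(co$subjects, subjectId, character(1))))
  expect_identical(unique(info$protocol), "sim")
})

test_that("embedding returns one finite coordinate pair per record, deterministically", {
  withr::with_seed(1, {
    feats <- rbind(matrix(rnorm(200 * 6), 200), matrix(rnorm(200 * 6) + 8, 200))
  })
  ms <- new("ModeSet", halfModes = matrix(complex(real = feats[, 1:3],
                                                  imaginary = feats[, 4:6]),
                                          400, 3),
            features = feats,
            info = data.frame(subjectId = "s", group = rep(c("A", "B"), 200),
                              protocol = "p", modeIndex = 1:400,
                              frequencyHz = 0, eigRe = 1, eigIm = 0),
            embedding = matrix(0, 0, 2), nRoi = 3L)
  e1 <- embedModes(ms, perplexity = 20, seed = 5)
  e2 <- embedModes(ms, perplexity = 20, seed = 5)
  emb <- modeEmbedding(e1)
  expect_identical(dim(emb), c(400L, 2L))
  expect_true(all(is.finite(emb)))
  expect_identical(emb, modeEmbedding(e2))
  expect_error(embedModes(ms, perplexity = 200, seed = 1),
               "perplexity")
})

test_that("well-separated feature clusters stay separated in the embedding", {
  skip_if_not_installed("cluster")
  withr::with_seed(2, {
    feats <- rbind(matrix(rnorm(300 * 10, sd = 1), 300),
                   matrix(rnorm(300 * 10, sd = 1) + 20 / sqrt(10), 300))
  })
  labels <- rep(1:2, each = 300)
  ms <- new("ModeSet",
            halfModes = matrix(complex(real = feats[, 1:5],
                                       imaginary = feats[, 6:10]), 600, 5),
            features = feats,
            info = data.frame(subjectId = "s", group = "A", protocol = "p",
                              modeIndex = 1:600, frequencyHz = 0,
                              eigRe = 1, eigIm = 0),
            embedding = matrix(0, 0, 2), nRoi = 5L)
  emb <- modeEmbedding(embedModes(ms, perplexity = 30, seed = 3))
  sil <- cluster::silhouette(labels, dist(emb))
  expect_gt(mean(sil[, "sil_width"]), 0.5)
})

test_that("peak separation score counts planted density peaks", {
  withr::with_seed(4, {
    one <- matrix(rnorm(400), ncol = 2)
    two <- rbind(matrix(rnorm(400), ncol = 2),
                 cbind(rnorm(200) + 10, rnorm(200)))
    centers <- rbind(c(0, 0), c(12, 0), c(0, 12))
    three <- do.call(rbind, lapply(1:3, function(k)
      cbind(rnorm(300) + centers[k, 1], rnorm(300) + centers[k, 2])))
  })
  expect_identical(peakSeparationScore(one), 1L)
  expect_identical(peakSeparationScore(two), 2L)
  expect_identical(peakSeparationScore(three), 3L)
})

test_that("perplexity selection maximizes peak separation with deterministic ties", {
  withr::with_seed(5, {
    feats <- do.call(rbind, lapply(1:3, function(k)
      matrix(rnorm(150 * 8, mean = c(0, 12, -12)[k] / sqrt(8)), 150)))
  })
  ms <- new("ModeSet",
            halfModes = matrix(complex(real = feats[, 1:4],
                                       imaginary = feats[, 5:8]), 450, 4),
            features = feats,
            info = data.frame(subjectId = "s", group = "A", protocol = "p",
                              modeIndex = 1:450, frequencyHz = 0,
                              eigRe = 1, eigIm = 0),
            embedding = matrix(0, 0, 2), nRoi = 4L)
  one <- selectPerplexity(ms, grid = 25, seed = 1)
  expect_equal(one$perplexity, 25)
  sel <- selectPerplexity(ms, grid = c(5, 30), seed = 1)
  expect_true(sel$perplexity %in% c(5, 30))
  expect_equal(sel$scores[[as.character(sel$perplexity)]], max(sel$scores))
  sel2 <- selectPerplexity(ms, grid = c(5, 30), seed = 1)
  expect_identical(sel$perplexity, sel2$perplexity)
  expect_identical(modeEmbedding(sel$embedded), modeEmbedding(sel2$embedded))
})
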