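test_that("block spatial patterns are unit norm, near-orthogonal and exact in the no-overlap case", {
  p <- makeSpatialPatterns(4, 2, seed = 1, overlap = 0)
  expect_equal(p[[1]], c(1, 1, 0, 0) / sqrt(2), tolerance = 1e-12)
  expect_equal(p[[2]], c(0, 0, 1, 1) / sqrt(2), tolerance = 1e-12)

  p <- makeSpatialPatterns(60, 6, seed = 3)
  for (v in p) expect_equal(sqrt(sum(v^2)), 1, tolerance = 1e-12)
  P <- do.call(cbind, p)
  cors <- cor(P)
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.5)

  expect_identical(makeSpatialPatterns(30, 4, seed = 9),
                   makeSpatialPatterns(30, 4, seed = 9))
  expect_error(makeSpatialPatterns(3, 5), "nModes")
})

test_that("a noise-free single-mode subject is a pure sinusoid scaled by its pattern", {
  cfg <- tinyConfig(nModes = 1L, frequencies = 0.05, decayRates = 1,
                    occurrenceProbA = 1, occurrenceProbB = 1,
                    noiseSd = 0, nConfounds = 0L, dt = 2)
  ts <- generateSubject(cfg, "A", seed = 4)
  X <- tsData(ts)
  pat <- makeSpatialPatterns(cfg$nRoi, 1L, seed = cfg$seed)[[1]]
  # every ROI trace must be the same sinusoid scaled by its pattern weight
  ref <- X[which.max(abs(pat)), ] / pat[which.max(abs(pat))]
  for (r in seq_len(nrow(X)))
    expect_equal(X[r, ], pat[r] * ref, tolerance = 1e-10)
  # and ref must be a pure 0.05 Hz sinusoid: projecting onto the two
  # quadrature components reproduces it exactly
  tIdx <- 0:(ncol(X) - 1)
  D <- cbind(cos(2 * pi * 0.05 * 2 * tIdx), sin(2 * pi * 0.05 * 2 * tIdx))
  fit <- D %*% qr.solve(D, ref)
  expect_equal(as.numeric(fit), ref, tolerance = 1e-8)
})

test_that("all-zero occurrence probabilities leave pure noise plus confounds", {
  cfg <- tinyConfig(occurrenceProbA = rep(0, 3), occurrenceProbB = rep(0, 3),
                    noiseSd = 0, nConfounds = 2L)
  ts <- generateSubject(cfg, "A", seed = 5)
  # with zero noise the signal must lie entirely in the confound span
  X <- tsData(ts)
  C <- ts@confounds
  resid <- X - X %*% C %*% solve(crossprod(C)) %*% t(C)
  expect_lt(max(abs(resid)), 1e-8)
  expect_identical(attr(ts, "activeModes"), integer(0))
})

test_that("subject generation is deterministic given seed and group", {
  cfg <- tinyConfig()
  a1 <- generateSubject(cfg, "A", seed = 10)
  a2 <- generateSubject(cfg, "A", seed = 10)
  expect_identical(tsData(a1), tsData(a2))
  expect_identical(a1@confounds, a2@confounds)
})

test_that("noise-free stable subjects have rank at most 2 x active modes + confounds", {
  cfg <- tinyConfig(decayRates = c(1, 1, 1), noiseSd = 0, nConfounds = 1L,
                    occurrenceProbA = rep(1, 3))
  ts <- generateSubject(cfg, "A", seed = 2)
  sv <- svd(tsData(ts))$d
  bound <- 2L * length(attr(ts, "activeModes")) + cfg$nConfounds
  expect_lte(sum(sv > 1e-8 * sv[1]), bound)
})

test_that("cohorts carry labels, ground truth and forced active sets", {
  cfg <- tinyConfig(nSubjectsPerGroup = 3L)
  co <- generateCohort(cfg)
  expect_length(co$subjects, 6L)
  expect_identical(vapply(co$subjects, groupLabel, character(1)),
                   rep(c("A", "B"), each = 3L))
  expect_length(co$groundTruth$differentialModes, 0L)

  cfg2 <- tinyConfig(occurrenceProbA = c(1, 0, 0),
                     occurrenceProbB = c(0, 1, 0))
  co2 <- generateCohort(cfg2)
  act <- co2$groundTruth$activeModes
  grp <- vapply(co2$subjects, groupLabel, character(1))
  for (i in seq_along(act))
    expect_identical(act[[i]], if (grp[i] == "A") 1L else 2L)
  expect_identical(co2$groundTruth$differentialModes, c(1L, 2L))
})

test_that("per-mode activation frequency matches the configured probability", {
  cfg <- tinyConfig(nRoi = 6L, nTimepoints = 20L, nSubjectsPerGroup = 100L,
                    occurrenceProbA = c(0.3, 0.7, 0.5),
                    occurrenceProbB = c(0.3, 0.7, 0.5),
                    noiseSd = 0.05, nConfounds = 0L)
  co <- generateCohort(cfg)
  act <- co$groundTruth$activeModes
  n <- length(act)  # 200 subjects
  for (m in 1:3) {
    phat <- mean(vapply(act, function(a) m %in% a, logical(1)))
    p <- cfg$occurrenceProbA[m]
    expect_lt(abs(phat - p), 4 * sqrt(p * (1 - p) / n))
  }
})

test_that("confound series are centered, reproducible and empty when q = 0", {
  expect_identical(dim(generateConfounds(30, 0)), c(30L, 0L))
  C <- generateConfounds(200, 3, seed = 6)
  expect_lt(max(abs(colMeans(C))), 1e-10)
  expect_identical(C, generateConfounds(200, 3, seed = 6))
  expect_equal(qr(C)$rank, 3L)
})

test_that("invalid configurations are rejected with informative messages", {
  expect_error(tinyConfig(frequencies = c(0.03, 0.3, 0.2)), "Nyquist|inside")
  expect_error(tinyConfig(decayRates = c(1, 1.2, 0.9)), "decayRates")
  expect_error(tinyConfig(occurrenceProbA = c(0.5, 0.5)), "length")
  expect_error(tinyConfig(nModes = 20L), "nModes")
})
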