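# A hand-built ModeSet with controlled amplitudes/phases for summaries.
mkModeSet <- function(halfModes, group, protocol, freq) {
  n <- nrow(halfModes)
  new("ModeSet", halfModes = halfModes,
      features = cbind(Re(halfModes), Im(halfModes)),
      info = data.frame(subjectId = sprintf("s%02d", seq_len(n)),
                        group = group, protocol = protocol,
                        modeIndex = seq_len(n), frequencyHz = freq,
                        eigRe = 0.99, eigIm = 0.05),
      embedding = matrix(0, n, 2), nRoi = ncol(halfModes))
}

test_that("a single-member cluster reproduces that mode's amplitudes exactly", {
  half <- matrix(c(0.5 + 0.1i, -0.2 + 0.3i, 0.05 - 0.4i), 1, 3)
  ms <- mkModeSet(half, "A", "p1", 0.04)
  cl <- list(clusterId = 1L, members = 1L, direction = "AoverB",
             centroid = c(0, 0), size = 1L)
  s <- clusterSummary(cl, ms, dt = 2)
  expect_equal(s$meanAmplitude, Mod(half[1, ]), tolerance = 1e-12)
  expect_equal(s$circularPhase, Arg(half[1, ]), tolerance = 1e-12)
  expect_true(all(s$phaseDefined))
  expect_identical(sum(s$freqCounts), 1L)
})

test_that("antiphase pairs keep amplitude but lose a defined phase", {
  z <- c(0.4 + 0.2i, -0.1 + 0.5i)
  half <- rbind(z, -z)   # identical amplitudes, exactly opposite phases
  ms <- mkModeSet(half, "A", "p1", c(0.03, -0.03))
  cl <- list(clusterId = 1L, members = 1:2, direction = "AoverB",
             centroid = c(0, 0), size = 2L)
  s <- clusterSummary(cl, ms, dt = 2)
  expect_equal(s$meanAmplitude, Mod(z), tolerance = 1e-12)
  expect_false(any(s$phaseDefined))
  expect_equal(s$circularPhase, c(0, 0))
  # conjugate-pair frequencies fold into one |f| bin
  expect_identical(sum(s$freqCounts), 2L)
  expect_identical(s$freqCounts[4], 2L)  # |0.03| lands in [0.03, 0.04)
})

test_that("eigenvalues pass through for stability inspection", {
  half <- matrix(complex(real = rnorm(6), imaginary = rnorm(6)) / 4, 3, 2)
  ms <- mkModeSet(half, "B", "p1", c(0.1, 0.12, 0.14))
  ms@info$eigRe <- c(0.985, 0.99, 0.995)
  ms@info$eigIm <- c(0.1, 0.05, 0.02)
  cl <- list(clusterId = 1L, members = 1:3, direction = "BoverA",
             centroid = c(0, 0), size = 3L)
  s <- clusterSummary(cl, ms, dt = 2)
  expect_true(all(Mod(s$eigenvalues) <= 1 + 1e-9))
  expect_identical(length(s$eigenvalues), 3L)
})

test_that("summaries are invariant to member order and amplitudes bounded for unit modes", {
  cfg <- tinyConfig(noiseSd = 0.05)
  d <- dmdSubject(preprocessSubject(generateSubject(cfg, "A", seed = 4)))
  ms <- poolModes(list(d))
  cl1 <- list(clusterId = 1L, members = 1:6, direction = "AoverB",
              centroid = c(0, 0), size = 6L)
  cl2 <- list(clusterId = 1L, members = 6:1, direction = "AoverB",
              centroid = c(0, 0), size = 6L)
  s1 <- clusterSummary(cl1, ms, dt = 2)
  s2 <- clusterSummary(cl2, ms, dt = 2)
  expect_equal(s1$meanAmplitude, s2$meanAmplitude, tolerance = 1e-12)
  expect_equal(s1$freqCounts, s2$freqCounts)
  expect_true(all(s1$meanAmplitude >= 0 & s1$meanAmplitude <= 1))
  expect_error(clusterSummary(list(clusterId = 1, members = integer(0)),
                              ms, dt = 2), "empty")
})

test_that("per-protocol normalized counts are exact quotients summing at most one", {
  half <- matrix(complex(real = rnorm(40), imaginary = rnorm(40)) / 7,
                 20, 2)
  ms <- mkModeSet(half, rep(c("A", "B"), 10),
                  rep(c("P", "Q"), each = 10), 0.05)
  clP <- list(clusterId = 1L, members = 1:3, direction = "AoverB",
              centroid = c(0, 0), size = 3L)
  counts <- protocolNormalizedCounts(clP, ms)
  expect_equal(unname(counts["P"]), 0.3)
  expect_equal(unname(counts["Q"]), 0)
  # disjoint clusters: per-protocol sums cannot exceed one
  clQ <- list(clusterId = 2L, members = 11:20, direction = "AoverB",
              centroid = c(0, 0), size = 10L)
  total <- protocolNormalizedCounts(clP, ms) + protocolNormalizedCounts(clQ, ms)
  expect_true(all(total <= 1 + 1e-12))
})

test_that("written reports round-trip their values", {
  half <- matrix(complex(real = rnorm(30), imaginary = rnorm(30)) / 6, 10, 3)
  ms <- mkModeSet(half, rep(c("A", "B"), 5), "P", seq(0.02, 0.2, length.out = 10))
  cl <- list(clusterId = 1L, members = 1:7, direction = "BoverA",
             centroid = c(0.5, -0.5), size = 7L)
  s <- clusterSummary(cl, ms, dt = 2)
  out <- withr::local_tempdir()
  writeReport(list(s), out)
  amp <- read.delim(file.path(out, "cluster_1_BoverA_amplitude.tsv"))
  expect_equal(amp$mean_amplitude, s$meanAmplitude, tolerance = 1e-12)
  expect_equal(amp$circular_phase, s$circularPhase, tolerance = 1e-12)
  hist <- read.delim(file.path(out, "cluster_1_BoverA_freq_hist.tsv"))
  expect_identical(sum(hist$count), 7L)
  digest <- jsonlite::read_json(file.path(out, "report.json"))
  expect_identical(digest$nClusters, 1L)
  expect_equal(digest$clusters$cluster_1_BoverA$size, 7)

  out2 <- withr::local_tempdir()
  writeReport(list(), out2)
  d2 <- jsonlite::read_json(file.path(out2, "report.json"))
  expect_identical(d2$nClusters, 0L)
  expect_false(file.exists(file.path(out2, "protocol_counts.tsv")))
})
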