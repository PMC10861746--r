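# Shared fixtures and independent reference implementations.

# Small default config for fast unit tests.
tinyConfig <- function(...) {
  args <- list(nRoi = 12L, nTimepoints = 60L, nModes = 3L,
               frequencies = c(0.03, 0.1, 0.2),
               decayRates = c(1, 0.99, 0.98),
               occurrenceProbA = rep(0.6, 3), occurrenceProbB = rep(0.6, 3),
               nSubjectsPerGroup = 3L, nConfounds = 1L, seed = 7L)
  override <- list(...)
  args[names(override)] <- override
  do.call(syntheticConfig, args)
}

# Noise-free multi-oscillator data with known propagator eigenvalues:
# x_t = sum_j c_j r_j^t cos(2 pi f_j dt t + th_j) v_j.
# True nonzero eigenvalues of the one-step propagator on the delay-stacked
# state are r_j exp(+/- 2 pi i f_j dt).
makeLinearData <- function(nRoi, nT, freqs, decays, dt = 2, seed = 1) {
  withr::with_seed(seed, {
    V <- qr.Q(qr(matrix(rnorm(nRoi * length(freqs)), nRoi)))
    tIdx <- 0:(nT - 1)
    X <- matrix(0, nRoi, nT)
    for (j in seq_along(freqs)) {
      th <- runif(1, 0, 2 * pi)
      cj <- runif(1, 0.5, 1.5)
      X <- X + outer(V[, j], cj * decays[j]^tIdx *
                       cos(2 * pi * freqs[j] * dt * tIdx + th))
    }
    truth <- c(decays * exp(2i * pi * freqs * dt),
               decays * exp(-2i * pi * freqs * dt))
    list(ts = ROITimeSeries(X, dt = dt, subjectId = "lin", group = "A"),
         trueEigenvalues = truth, trueFrequencies = c(freqs, -freqs))
  })
}

# Brute-force DBSCAN reference: core points from neighbourhood counts,
# clusters = connected components of the eps-graph restricted to core
# points; border points join the cluster of the earliest-seeded core
# neighbour (seeds scanned in index order) — the documented tie-break.
bruteDbscan <- function(points, eps, minSamples) {
  n <- nrow(points)
  d <- as.matrix(dist(points))
  within <- d <= eps
  core <- rowSums(within) >= minSamples
  labels <- integer(n)
  cid <- 0L
  seedOrder <- integer(0)
  # connected components over core points, seeded in index order
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cid <- cid + 1L
    comp <- i
    repeat {
      grow <- which(core & labels == 0L &
                      apply(within[, comp, drop = FALSE], 1L, any))
      grow <- setdiff(grow, comp)
      if (!length(grow)) break
      comp <- c(comp, grow)
    }
    labels[comp] <- cid
  }
  # border points: earliest-seeded cluster among core neighbours
  for (i in which(!core)) {
    nb <- which(core & within[i, ])
    if (length(nb)) labels[i] <- min(labels[nb])
  }
  labels
}

# Same-partition check that is robust to cluster id relabelling.
samePartition <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (!identical(a == 0L, b == 0L)) return(FALSE)
  ok <- TRUE
  for (k in setdiff(unique(a), 0L)) {
    members <- which(a == k)
    ok <- ok && length(unique(b[members])) == 1L
  }
  for (k in setdiff(unique(b), 0L)) {
    members <- which(b == k)
    ok <- ok && length(unique(a[members])) == 1L
  }
  ok
}

# Minimal DMDResult for feature-construction tests.
manualDMDResult <- function(halfEntries, eigenvalue = 0.9 + 0.1i, dt = 2) {
  nroi <- length(halfEntries)
  mode <- c(halfEntries, eigenvalue * halfEntries)
  mode <- mode / sqrt(sum(Mod(mode)^2))
  new("DMDResult", modes = matrix(mode, ncol = 1L),
      eigenvalues = as.complex(eigenvalue),
      frequencies = eigenvalueFrequency(eigenvalue, dt),
      subjectId = "manual", group = "A", protocol = "p", dt = dt,
      nRoi = as.integer(nroi))
}
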