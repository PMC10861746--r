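# modeScape

Cohort comparison of brain dynamic modes on a two-dimensional manifold.

## What it does

Resting-state fMRI studies often summarize each subject by static
functional connectivity, discarding oscillatory temporal structure.
modeScape implements an alternative pipeline for two-cohort studies
(e.g. patients vs controls) of parcellated BOLD time series:

1. **Conditioning** — per ROI: linear detrend, nuisance regression
   (motion/global-signal/CompCor-style series, intercept included),
   z-scoring. No band-pass filter: frequency content is recovered from
   the eigenvalues downstream.
2. **One-stacked time-delay DMD** — each subject's series is augmented
   with its one-step shift and decomposed exactly:
   `X1aug = UΣV*`, `Ã = U*X2aug VΣ⁻¹`, `ÃW = WΛ`, `Φ = X2aug VΣ⁻¹W`.
   Columns of `Φ` are dynamic modes (coherent complex spatial
   patterns); each eigenvalue `λ` gives a frequency
   `f = Im(ln λ)/(2πΔt)` and a per-step decay `|λ|`.
3. **Manifold** — all modes of all subjects are pooled; the first
   `Nroi` complex entries are split into real/imaginary stacks and
   embedded in 2-D with t-SNE (perplexity selected automatically by
   counting separated density peaks, or fixed).
4. **Density ratio** — the two cohorts' point clouds are compared by
   direct density-ratio estimation (uLSIF, Gaussian kernels on ≤ 100
   centers, 5-fold CV over kernel width and ridge penalty), in both
   directions; per-cohort Gaussian KDEs (Scott's rule) are also fitted.
5. **Inference** — a max-statistic permutation null (cohort labels
   shuffled across subjects by default, so all of a subject's modes
   move together; ratio refitted at the observed-selected (σ, η),
   maximum of the surface recorded) sets a 95th-percentile threshold;
   modes above it are clustered with DBSCAN (noise discarded).
   Mode-level shuffling is available but anticonservative under
   within-subject dependence.
6. **Report** — per cluster: per-ROI mean amplitude and circular mean
   phase, |f| histogram (0.01 Hz bins), eigenvalues for unit-circle
   inspection, cohort composition, per-protocol normalized counts.

A synthetic two-cohort generator with known ground truth (planted
damped oscillatory modes occurring with cohort-specific probabilities)
supports end-to-end parameter-recovery testing; real data enter as
plain TSV matrices via a cohort manifest.

## Worked example

```r
library(modeScape)

cfg <- pipelineConfig(
  synthetic = syntheticConfig(
    nRoi = 36, nTimepoints = 120, nSubjectsPerGroup = 40,
    occurrenceProbA = c(0.9, rep(0.5, 5)),   # mode 1 common in cohort A
    occurrenceProbB = c(0.2, rep(0.5, 5)),   # ... rare in cohort B
    seed = 1),
  perplexity = 30, gridResolution = 100, nPerm = 50,
  epsBoverA = 0.5, epsAoverB = 0.5, seed = 42)

res <- runPipeline(cfg, "run1")
res$modeSet
#> ModeSet: 5760 pooled dynamic modes over 36 ROIs
#>   modes per group: A=2880, B=2880
#>   embedded: yes
res$thresholds
#> $BoverA
#> [1] 1.928292
#> $AoverB
#> [1] 1.980111
length(res$clusters$AoverB)   # clusters enriched in cohort A
#> [1] 1
```

The single A-enriched cluster contains 29 modes, 100% of them from
subjects carrying the planted differential mode, with mean
|f| = 0.0162 Hz against the planted 0.02 Hz — the pipeline has located
the mode whose occurrence differs between the cohorts and read off its
frequency. Its per-ROI mean amplitudes concentrate on the planted
spatial block (≈ 0.27–0.29 on the block's six ROIs, near zero
elsewhere). All artifacts (embedding, density/ratio fields, null
maxima, thresholds, cluster assignments, per-cluster TSVs,
`report.json`) are written under the run directory, and the run is
byte-reproducible from the master seed.

A thin command-line wrapper is included:

```sh
Rscript inst/scripts/run_pipeline.R --config cfg.yaml --out run1 --seed 42
```

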