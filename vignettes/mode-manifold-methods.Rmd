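---
title: "Methods: cohort comparison of brain dynamic modes on a 2-D manifold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cohort comparison of brain dynamic modes on a 2-D manifold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modeScape)
```

## The question and the model

Resting-state fMRI gives, per subject, a matrix of parcellated BOLD
signals: `Nroi` regions of interest by `NT` time points sampled every
`dt` seconds. Classical functional-connectivity summaries discard
oscillatory temporal structure. modeScape instead treats each subject's
recording as the output of an approximately linear dynamical system and
asks whether two cohorts (labelled A and B, e.g. healthy controls and
patients) differ in *how often* particular spatio-temporal patterns —
dynamic modes — occur.

The per-subject decomposition is one-stacked time-delay-coordinates
dynamic mode decomposition (tdcDMD). Snapshots are augmented with their
one-step successors,

$$X_{1,\mathrm{aug}} = \begin{bmatrix} x_1 & \cdots & x_{N_T-2}\\
x_2 & \cdots & x_{N_T-1}\end{bmatrix},\qquad
X_{2,\mathrm{aug}} = \begin{bmatrix} x_2 & \cdots & x_{N_T-1}\\
x_3 & \cdots & x_{N_T}\end{bmatrix},$$

and the best-fit linear propagator $A$ with
$X_{2,\mathrm{aug}} \approx A X_{1,\mathrm{aug}}$ is diagonalized
through the SVD $X_{1,\mathrm{aug}} = U\Sigma V^*$, the reduced operator
$\tilde A = U^* X_{2,\mathrm{aug}} V \Sigma^{-1}$, its eigenpairs
$\tilde A W = W\Lambda$, and the exact modes
$\Phi = X_{2,\mathrm{aug}} V \Sigma^{-1} W$. Each eigenvalue
$\lambda_i$ encodes a frequency on the principal branch,

$$f_i = \frac{\operatorname{Im}\,\ln \lambda_i}{2\pi\,\Delta t}
\in \left(-\tfrac{1}{2\Delta t}, \tfrac{1}{2\Delta t}\right],$$

and a per-step growth/decay $|\lambda_i|$. The single delay stack is
what lets a real standing wave — rank-2 dynamics whose spatial pattern
alone is rank-1 — be resolved; for real input, modes come in conjugate
pairs with identical amplitude and opposite phase.

Modes from all subjects of both cohorts are pooled. Only the first
`Nroi` entries of each `2*Nroi`-long mode enter the downstream analysis
(the second block duplicates the first up to one application of the
propagator); real and imaginary parts are stacked into a `2*Nroi`
real feature vector — an exact isometry of the complex half-mode. t-SNE
maps the pooled features to two dimensions, and cohort differences are
then differences between the two point clouds on that manifold:

* per-cohort density via a Gaussian KDE with Scott's rule
  (bandwidth matrix = sample covariance times $n^{-1/3}$, i.e. the
  squared Scott factor $n^{-1/6}$ in two dimensions, normalized so the
  density integrates to one and is comparable across cohort sizes);
* the *density ratio* in both directions by direct estimation —
  unconstrained least-squares importance fitting (uLSIF), the
  $\alpha = 0$ case of the relative variant. Fitting the ratio
  $r(x) = p_\mathrm{num}(x)/p_\mathrm{den}(x)$ directly as a Gaussian
  kernel expansion on up to 100 numerator-drawn centers is more accurate
  than dividing two separately estimated densities, which the test suite
  verifies against the closed-form ratio of two Gaussians;
* significance by a max-statistic permutation test: cohort labels of the
  embedded modes are shuffled (group sizes preserved), the ratio is
  refitted at fixed kernel width and ridge penalty, and the maximum of
  the fitted surface over an evaluation grid is recorded; the 95th
  percentile of the null maxima (linear-interpolation percentile rule)
  is the threshold. Modes whose own embedded coordinate exceeds the
  threshold are clustered with DBSCAN; noise points are discarded, and
  each surviving cluster is summarized by per-ROI mean amplitude,
  per-ROI circular mean phase, an |f| histogram in 0.01 Hz bins, its
  eigenvalues, cohort composition and per-protocol normalized counts.

A ratio direction is named for its numerator: peaks of the B-over-A
surface mark regions where cohort B's modes are over-represented.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `rankTol` | `1e-10` | relative SVD cutoff; regularizes the pseudo-inverse without discarding genuine dynamics |
| `perplexity` | `"auto"` over {10, 30, 100, 300} | t-SNE neighbourhood size; selected by counting separated KDE peaks of the embedding |
| `sigmaGrid` | `c(1.2, 1.0, 0.8)` × local scale | uLSIF kernel widths; the reference values presume embeddings of very large mode collections, so below 20,000 modes they are rescaled by the embedding's median 10th-nearest-neighbour distance |
| `etaGrid` | `0.10, 0.09, ..., 0.01` | ridge penalties searched by 5-fold CV of the least-squares criterion J |
| `permSigma`, `permEta` | observed-selected | the permutation null reuses, per direction, the (σ, η) chosen by CV on the observed data; model selection is not repeated under the null |
| `nPerm` | 100 | permutations per direction |
| `permutationLevel` | `"subject"` | labels shuffled across subjects (blocked) or across individual modes (`"mode"`, the reference procedure; anticonservative under within-subject dependence) |
| `percentile` | 0.95 | significance percentile of the null maxima |
| `gridResolution` | 200 | evaluation-grid nodes per axis for density/ratio surfaces and the max statistic |
| DBSCAN `(eps, minSamples)` | B-over-A (1, 100); A-over-B (0.15, 300) | reference values for ~160,000 pooled modes; with `scaleClusterParams = TRUE` eps is multiplied by the embedding's local scale and minSamples by n/160000 (floor 5) |

The z-score step guarantees the unit-variance contract the DMD
receives, so conditioning runs detrend → confound regression (intercept
always included) → z-score; the order matters only for the final
variance normalization and is a documented package choice — whether the
reference pipelines z-score before or after nuisance regression is
generally unstated. No band-pass filter is applied anywhere: the
eigenvalues themselves carry the frequency content, and the tests check
that a 0.2 Hz component survives conditioning intact.

## The synthetic generator

Real multi-site rsfMRI cohorts of the size this method targets are
access-restricted, so the package ships a generator whose draws match
the hypothesis class of the decomposition: each subject is

$$X_{\cdot t} = \sum_{m \in \text{active}} c_m\, r_m^{\,t}
\cos(2\pi f_m \Delta t\, t + \theta_m)\, v_m + L\,C_t + \varepsilon_t,$$

with unit-norm block spatial patterns $v_m$ (contiguous ROI blocks with
small random spill-over, pairwise correlation < 0.5), per-subject
amplitude $c_m \sim U[0.5, 1.5]\cdot\text{amplitudeScale}$ and phase
$\theta_m \sim U[0, 2\pi)$, random-walk confound series $C$ with
Gaussian loadings $L$, and i.i.d. Gaussian noise $\varepsilon$. Mode
$m$ is active in a subject with its cohort's occurrence probability —
cohorts differ in how often modes occur, never in the modes themselves,
which is precisely the effect the pipeline is meant to detect. Real
sinusoids (conjugate-pair form) are planted so that the downstream DMD
of real data produces the paired ±f spectra the method expects.

Defaults: 60 ROIs, 150 time points at `dt = 2` s, six modes at
0.02–0.20 Hz (all below the 0.25 Hz Nyquist), decay rates 0.97–1,
`amplitudeScale = 1`, `noiseSd = 0.2`, two confound series. The noise
default is deliberate: the generator's purpose is parameter-recovery
testing, which requires that one subject's estimate of a planted mode
resemble another subject's estimate of the same mode while leaving
plenty of genuinely subject-specific variation. At `noiseSd = 0.2`
(roughly unit signal-to-noise per active-block ROI before z-scoring)
the between-subject cosine similarity of planted-mode features is
≈ 0.6 and per-subject frequency estimates scatter with sd ≈ 0.01 Hz.
At several times this noise level the pooled features no longer
cluster by planted mode and no manifold method could recover the
ground truth.

What the generator does *not* emulate: hemodynamic response functions,
neural-mass nonlinearity, spatially correlated physiological noise,
scanner-specific spectral signatures (protocols differ only by a tag),
or non-stationary mode switching within a scan. Passing recovery tests
on this generator therefore demonstrates correctness of the machinery
under its own modelling assumptions, not validity of those assumptions
for real BOLD data.

## Numerical choices and degenerate inputs

* **Confounds are detrended with the data.** Inside
  `preprocessSubject()` the confound series pass through the same
  detrending projection as the signals before regression. Regressing
  raw confounds out of detrended data would leave the confounds' own
  linear-trend component behind — a global low-frequency artifact that
  can dominate the per-subject SVD — which is why standard fMRI
  cleaning utilities detrend signals and nuisance series jointly.
* **Mode scale and phase.** DMD leaves mode scale and global phase
  arbitrary; modes are normalized to unit Euclidean norm over their
  `2*Nroi` entries and rotated so the largest-magnitude entry is real
  positive. This makes conjugate pairing exact and reports
  deterministic. Eigenvalues of numerically zero modulus (< 1e-12) are
  dropped; zero-frequency real eigenvalues are retained.
* **KDE degeneracies.** A two-point sample (whose covariance is always
  singular) falls back to a diagonal bandwidth with floored per-axis
  variances; larger collinear samples are rejected with advice to
  jitter. Evaluation grids enforce a minimal box width of 1e-6.
* **uLSIF.** The ridge makes the linear system strictly positive
  definite for every η > 0; predictions are clipped at zero because the
  least-squares fit can go negative — peak statistics depend on this
  clipping, which is why it is part of the contract. CV ties resolve to
  the first grid pair in order (σ varying slowest).
* **Percentile rule.** Null-maxima percentiles use linear interpolation
  between order statistics (type 7); e.g. maxima 1..100 give a 95th
  percentile of 95.05.
* **DBSCAN determinism.** Core points are scanned in index order;
  border points join the earliest-seeded neighbouring cluster. The test
  suite checks exact partition agreement with a brute-force eps-graph
  reference on random point sets.
* **Seeding.** Every stochastic stage derives its seed from the master
  seed and the stage name, so a full run is byte-reproducible and
  stages can be rerun in isolation.
* **Significance membership.** Significance is assessed at each mode's
  own embedded coordinate (strictly above threshold), avoiding an
  arbitrary region-growing definition of "significant areas".
* **Permutation level.** The permutation null shuffles cohort labels at
  the *subject* level by default: all modes of a subject move together.
  Modes within a subject are strongly dependent — conjugate pairs
  always share a label, and a subject's whole mode profile reflects
  which dynamics were active in that scan — so shuffling at the mode
  level underdisperses the null and is anticonservative. On null
  synthetic cohorts (equal occurrence probabilities, 30 subjects per
  group) the mode-level null yields a spurious significant cluster in
  roughly 9 of 10 studies, the subject-level null in about 1 of 10 at
  the nominal 5% level. `permutationLevel = "mode"` remains available
  as the reference procedure. The calibrated null costs power: the
  subject-level threshold reflects genuine between-subject occurrence
  variability, which is the quantity the method makes claims about.
* **Per-direction thresholds.** Each ratio direction gets its own
  permutation null and threshold; directions are never pooled.

## Design choices that were genuinely open

* **Perplexity selection.** The reference procedure selects perplexity
  visually. The automated stand-in embeds at each candidate and counts
  separated KDE peaks on a 100×100 grid (peaks above 20% of the global
  maximum, ≥ 2 cells apart), choosing the candidate with the most
  peaks, ties to the smallest. The 100×100/20% values are documented
  and configurable rather than principled.
* **Generative model.** No accepted forward model links neural activity
  to parcel BOLD at this granularity; the linear damped-oscillator form
  was chosen to match the decomposition's hypothesis class, and is not
  claimed to match fMRI physiology.
* **Cluster summaries.** Mean amplitude and circular mean phase are
  computed separately per ROI, because naive complex averaging would
  cancel under the antiphase pairing that is intrinsic to real-data
  modes; a phase is flagged undefined when the circular resultant
  length is below 0.1. Frequency histograms fold conjugate pairs via
  |f|.
* **Ratio-direction semantics.** "Ratio for cohort G" always means G in
  the numerator, so peaks mark G-enriched regions; both directions are
  always computed and reported separately.

## Problem sizes used by the shipped tests

The validation suite runs at desk scale, chosen once as the package's
own test conditions: unit tests use 12–30 ROIs and 60–120 time points;
the type-I check runs 20 null cohorts of 30 subjects per group (20
ROIs, 100 time points, 50 permutations); the end-to-end recovery check
runs 10 seeded studies of 40 subjects per group (36 ROIs, 120 time
points, six planted modes, occurrence 0.9 vs 0.2 for the differential
mode, 50 permutations) and requires the enriched-direction cluster to
consist of > 80% carrier modes with mean |f| within 0.01 Hz of the
planted frequency. Both checks use the calibrated subject-level null.
At these sizes DBSCAN's scaled radii are symmetric across directions
(0.5–1 local-scale unit, minSamples floor 5); 36 ROIs keeps the
per-mode block size at six ROIs, enough signal per planted mode for
its ratio peak to clear the subject-level threshold reliably. A short worked example at the same scale appears in the
README, and `scripts/acceptance.R` reruns the full set of calibration
and recovery computations from scratch.

## Known limitations

* t-SNE is O(n²) in time at `theta = 0` and approximate above; very
  large pooled collections (> 10^5 modes) need hours and substantial
  memory, which is intrinsic to the approach.
* The max-statistic permutation null controls the familywise rate of
  *any* false cluster per direction, not per-cluster error, and
  mode-level shuffling ignores within-subject dependence.
* uLSIF with 100 centers caps the complexity of the ratio surface;
  extremely narrow enrichment regions can be over-smoothed at the CV
  selected kernel width.
* Frequency estimates inherit DMD's noise-induced eigenvalue damping
  bias: with measurement noise, |λ| is biased below its true value and
  frequencies scatter; cluster-level averaging mitigates but does not
  remove this.
* The calibrated (subject-level) permutation test trades power for
  validity: at desk scale (40 subjects per group, occurrence 0.9 vs
  0.2 for one of six planted modes) the shipped recovery check
  succeeds in about 7 of 10 seeded studies — the enriched region's
  estimated ratio peak sits close to the significance threshold, and
  sampling variability tips individual studies either way. The
  mode-level reference null detects the same effect far more often,
  but only because it is anticonservative.
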