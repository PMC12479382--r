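---
title: "Methods: functional connectivity, cortical gradients, and pre/post contrasts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: functional connectivity, cortical gradients, and pre/post contrasts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcgrad)
```

## Scope and model

`fcgrad` analyzes parcellated resting-state fMRI from a two-group
(drug / placebo), two-session (pre / post intervention) design. The unit of
analysis is a scan: a frames-by-parcels matrix of BOLD signal at a known
repetition time (TR), accompanied by rigid-body motion parameters, a
framewise-displacement (FD) trace, and a parcel-to-network atlas mapping
400 Schaefer-style parcels to six canonical resting-state networks (VIS,
ASM, DAN, SAL, FPN, DMN; the limbic network is excluded for its low
reproducibility and signal-to-noise ratio). The pipeline runs

denoise → functional connectivity → diffusion-map gradients → dispersion →
pre/post × group contrasts → brain–behavior association,

and a synthetic-cohort generator plants known covariance structure so that
every stage can be verified against closed-form ground truth. Everything
operates at parcel resolution: voxel/surface preprocessing (motion
correction, normalization, smoothing, surface projection) is upstream and
out of scope, as is voxel-level cluster inference (see *Statistical
contrasts* below).

## Denoising

Each scan is cleaned in a fixed order:

1. **Spike flagging.** Frames with FD strictly greater than 0.5 mm are
   flagged; each flagged frame contributes one indicator ("spike")
   regressor. Flagged frames are deleted after filtering, before any
   correlation is computed.
2. **Nuisance regression.** Per parcel, ordinary-least-squares residuals
   against an intercept, the Friston 24-parameter motion expansion (6
   parameters, their one-frame lag backfilled with 0 at the first frame,
   and both sets squared), principal components of externally supplied
   noise channels retaining the smallest count that explains ≥ 50 % of
   their variance (the aCompCor50 rule), the spike indicators, and
   optionally the global mean signal (GSR). Rank-deficient designs are
   solved by pseudoinverse, so residuals are orthogonal to every regressor
   regardless of collinearity.
3. **Band-pass filtering** to 0.008–0.09 Hz: zero-phase frequency-domain
   masking with unit pass-band gain, a 2-bin raised-cosine taper at each
   band edge, and the DC component always removed. This gives an exact,
   testable frequency response; the reference implementation's
   simultaneous regression–filtering is not fully specified, so the
   explicit sequence above is this package's recorded choice.

Two design points deserve emphasis. First, at parcel resolution there are
no white-matter/CSF voxels, so component-based physiological correction
accepts dedicated noise channels (the synthetic generator emits them);
this preserves the shape of the recipe without volumetric data. Second,
the *continuous* nuisance regressors are band-pass filtered with the same
filter before regression (frequency-matched nuisance regression), while
spike indicators stay raw. Without this, filtering after regression
reintroduces nuisance-band variance and a second application of the chain
changes Fisher-z connectivity by 0.03–0.05 on clean data; with it, the
chain is idempotent to < 0.02 on scans with no flagged frames. On scans
*with* flagged frames exact idempotence is unattainable under this
operation order: zeroing spike frames and then filtering necessarily leaks
a small amount of energy into retained frames.

## Connectivity metrics

All correlations are Pearson over retained frames, capped at
|r| ≤ 1 − 10⁻⁵, and Fisher z-transformed (atanh); the cap keeps z finite
for degenerate (duplicated) parcels and the number of capped entries is
surfaced as a QC field.

- **FC matrix**: all parcel pairs (diagonal undefined).
- **Network seed map**: correlation of every parcel with the unweighted
  mean series of a seed network. An optional per-frame weight vector is
  accepted; with a single continuous resting condition the weighted GLM of
  the reference tooling reduces to plain bivariate correlation.
- **Within-network FC**: unweighted mean of the seed map over the seed
  network's own parcels (own-network parcels included — the parcel-level
  analog of masking a seed map with the network mask).
- **Between-network FC**: Fisher-z correlation between network mean series
  for all 15 pairs.
- **Global FC**: per-parcel row mean of the FC matrix excluding the
  diagonal.

## Cortical gradients

Starting from a scan's Fisher-z FC matrix:

1. **Row thresholding** keeps the top 10 % of off-diagonal entries per row
   (`ceil(density × (P − 1))`, ties broken toward lower parcel index) and
   zeroes the rest; the result is generally asymmetric and is used as-is.
2. **Cosine affinity** between thresholded rows; negative similarities are
   clipped to 0 (the Markov normalization needs a nonnegative kernel) and
   the clipped count is recorded.
3. **Diffusion map embedding** with α = 0.5: the kernel is density
   normalized (`W' = D⁻ᵅ W D⁻ᵅ`), the transition operator `M = D'⁻¹ W'` is
   diagonalized through its symmetric conjugate, the trivial constant
   eigenvector (λ = 1) is dropped, and each retained component is scaled by
   λ/(1 − λ) — the diffusion-time-0 convention of the reference toolbox.
   Ten components are computed; the first three are analyzed, with
   variance explained defined as eigenvalue fractions over the ten
   computed components. A disconnected affinity graph is an error that
   advises raising the density.
4. **Procrustes alignment**: each scan's (column-mean-centered) scores are
   aligned to a group template by a pure rotation/reflection — no
   isotropic scaling, which would distort dispersion magnitudes. The
   template is built from the baseline (pre) scans' mean embedding and
   refined for 10 iterations (align all scans, re-average); the summed
   squared disparity is non-increasing by construction.
5. **Dispersion** in the 3-D space of the first three aligned gradients:
   within-network dispersion is the sum of squared Euclidean distances of
   a network's parcels to the network centroid; between-network dispersion
   is the Euclidean distance between centroids. Both are invariant to any
   common rotation of the scores, which is why alignment without scaling
   matters.

## Statistical contrasts

Four contrasts are evaluated for any per-scan metric (within-network FC,
between-network pairs, global FC per parcel, dispersion):

- **Synergy** (group × time interaction): two-way repeated-measures ANOVA
  with group between subjects and time within subjects, computed from
  unweighted-cell (Type-III-style) sums of squares so the 19/20 imbalance
  is handled; on balanced data the interaction F equals the squared pooled
  t on per-subject post − pre differences, an identity the test suite
  checks to 10⁻⁸. Degrees of freedom are subject-level (interaction
  F(1, n − 2)).
- **Group differences post** : ANCOVA of post scores on group with the pre
  scores as covariate (group t, df = n − 3).
- **Meditation** (placebo: post > pre) and **Psychedelic-augmented
  meditation** (drug: post > pre): the source description of these
  within-group ANCOVAs is ambiguous about what varies as a covariate
  within one group's rows; this package's recorded reading regresses the
  within-group change on the group's own centered baseline and tests the
  intercept (the baseline-adjusted mean change, df = n₉ − 2). This is a
  design choice, not an inference of original intent.

Families of tests (15 network pairs; 6 networks; all parcels) are
corrected with Benjamini–Hochberg FDR at q = 0.05. Parcel-level BH
explicitly replaces voxel-level Gaussian-Random-Field cluster inference,
which requires smoothness estimation on voxel maps and is out of scope.
All tests are two-sided. Perfect-fit degeneracies (zero residual
variance) report t = 0, p = 1 for a zero coefficient rather than an
unstable ratio.

**Brain–behavior association**: per questionnaire, OLS of a per-subject
connectivity change on score, group, and score × group, with BH correction
across the questionnaire family (five in the emulated design) and
per-group Pearson/Spearman follow-up correlations. A delta mode replaces
the raw day-2 score with day-2 minus baseline.

## Synthetic cohort generator

The generator is the package's ground-truth instrument, emulating the
study skeleton: 19 drug + 20 placebo subjects, two sessions, 240 frames at
TR = 1.8 s, 400 parcels across the six analyzed networks (sizes 66 / 82 /
49 / 50 / 56 / 97, approximating Schaefer-400 network proportions with the
excluded limbic share reallocated).

Scans are drawn from a zero-mean multivariate normal with a block
covariance, Cholesky-transformed from white noise, then optionally
smoothed by a common AR(1) filter (coefficient 0.3 by default, a typical
BOLD smoothness at this TR). Because the same filter is applied to every
parcel, all contemporaneous cross-correlations — the planted truth — are
preserved exactly.

Couplings are planted on interpretable scales. `within_coupling` (default
0.25) is the correlation between two parcels of the same network.
`between_coupling` (default 0.05) is defined as the correlation between
two networks' *mean series*: parcel-level block entries are calibrated as
`c_ab = ρ_ab √(v_a v_b)` with `v = (1 + (n − 1)w)/n`, so the value
recovered by `between_network_fc()` equals the planted ρ exactly in closed
form — uncalibrated constant blocks would make the mean-series correlation
much larger than the parcel-level entry. Effect injections add a delta to
a pair's ρ (or a network's w) for one group × session cell; every implied
covariance is checked for positive definiteness at configuration time and
a violating injection is rejected by name. Coupling defaults are chosen
for test power (they give well-conditioned covariances and detectable
planted effects at n = 20/group), not to match empirical FC
distributions, which the source data do not report.

FD traces are folded-normal (mean 0.15, sd 0.05 mm) with independent
3 %-probability spikes of +0.7 mm — independent of the signal, since no
motion–signal coupling is specified. Motion parameters are small random
walks; five white-noise nuisance channels per scan feed the
component-based correction. Day-2 questionnaire scores are
linear-Gaussian in the subject's planted Fisher-z connectivity change
with group-specific slopes; baseline scores are intercept plus noise.

What the generator does *not* emulate: hemodynamic response shapes,
physiological waveforms, spatial autocorrelation within networks beyond
the block structure, heavy-tailed motion, or realistic questionnaire
distributions. Passing recovery tests therefore demonstrates correctness
of the estimators and calibration of the tests under the assumed model,
not robustness to real-data violations of it.

Two planted-geometry connectomes feed the gradient pipeline's recovery
tests: a **line** (connectivity decaying exponentially along a planted 1-D
coordinate; the first gradient must recover the coordinate's ordering) and
**two blocks** (strong within-, weak between-block connectivity; the first
gradient must separate the blocks with full sign purity). A small seeded
symmetric jitter breaks exact ties. Note that at P = 100 with two
50-parcel blocks, 10 % row density retains only within-block edges and the
affinity graph disconnects — the embedding then correctly refuses to run —
so the block-recovery analyses use density 0.6; the line analyses use the
default 0.10.

## Numerical choices and degenerate inputs

- Correlation cap 1 − 10⁻⁵ before atanh (z ≈ 6.1 for duplicates).
- Eigen-decompositions use the symmetric conjugate of the transition
  operator (LAPACK symmetric solver); the trivial eigenvector is identified
  structurally, not by tolerance.
- Procrustes uses the SVD solution of the orthogonal case only.
- Constant parcels, constant covariates, disconnected affinities,
  all-zero rows, and non-PD injections are hard errors naming the
  offending object; empty spike sets and empty rejection sets are valid
  results.
- First-frame backfill of lagged motion regressors is 0, fixed by
  convention.
- FD flagging uses strict inequality (FD > 0.5 mm).

## Problem sizes used in verification

The test-suite and acceptance simulations run the full estimator chain at
reduced parcel count (10 parcels per network, P = 60) with the design's
n = 20/group, T = 240, TR = 1.8 s: between-network FC depends only on
network mean series, whose planted correlation is exact under the
calibrated generator at any parcel count, so parcel count buys no
additional fidelity for those checks. Null calibration of the Synergy
interaction uses 500 replicate cohorts; planted-effect recovery
(Δr = 0.2 on VIS–SAL, post-only, drug group) uses 200. Embedding-oracle
and Procrustes checks use 60-parcel problems where dense reference
decompositions are exact.

## Known limitations

- Parcel resolution throughout: no voxel/surface maps, no cluster-extent
  inference, no anatomical labeling of effects.
- The within-group ANCOVA reading is one of several defensible
  interpretations of the source design (documented above).
- The RM-ANOVA uses subject-level degrees of freedom; tools that fit
  scan-level GLMs report larger denominator df for the same design.
- Variance-explained fractions are relative to the 10 computed
  components, not the full spectrum.
- The AR(1) noise model understates the low-frequency structure of real
  BOLD; null calibration under richer noise should be re-checked before
  applying the packaged thresholds to real data.
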