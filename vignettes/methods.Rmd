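---
title: "Sensor-space effective connectivity: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sensor-space effective connectivity: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Overview

`effconn` implements a sensor-space effective-connectivity analysis for
resting-state MEG, together with a complete synthetic-data generator so that
every stage can be exercised and validated without access to patient
recordings.  The chain is:

1. **RMS pairing** — the two planar gradiometers at each of the 102 helmet
   locations are collapsed to one orientation-free series,
   $y_\ell(t) = \sqrt{(x_a^2(t) + x_b^2(t))/2}$.
2. **PCA reduction** — the location series are mean-centred (not
   variance-scaled: paired gradiometers share units) and reduced to $K$
   principal components; the pipeline default is the first 60 components,
   which on realistic data carry more than 99% of the variance.
3. **MVAR fit** — a multivariate autoregressive model
   $z_t = \sum_{r=1}^{p} A_r z_{t-r} + \varepsilon_t$ is estimated with the
   Vieira–Morf lattice recursion; the order is either fixed (default
   $p = 8$) or selected by BIC,
   $\mathrm{BIC}(p) = n_\mathrm{eff}\,\ln\det\hat\Sigma_p + p\,d^2 \ln
   n_\mathrm{eff}$ with $n_\mathrm{eff} = n - p$.  Stationarity is checked
   with the stability index, the log spectral radius of the companion
   matrix; fits are accepted only when it is negative.
4. **Back-projection and PDC** — the fitted parameters are mapped back to
   location space through the orthonormal loadings,
   $\tilde A_r = L A_r L^\top$, and partial directed coherence is evaluated
   on a uniform grid (default every 0.1 Hz up to 80 Hz, i.e. 800 bins):
   $\pi_{ij}(f) = |\bar A_{ij}(f)| \big/ \sqrt{\sum_k |\bar A_{kj}(f)|^2}$
   with $\bar A(f) = I - \sum_r A_r e^{-i 2\pi f r / f_s}$.  This is the
   original column-normalized PDC; each source column has unit sum of
   squares at every frequency.
5. **Binarization and local efficiency** — per frequency bin the top 15% of
   off-diagonal PDC values become directed edges (ties broken by value,
   then ascending (row, column) index, so the graph is deterministic), and
   each node's local efficiency — the Latora–Marchiori efficiency of the
   directed subgraph induced on the union of its in- and out-neighbours,
   the node itself removed — yields a node-by-frequency efficiency map.
6. **Scalp×frequency images and group statistics** — node values are
   interpolated per bin onto a 64×64 grid (azimuthal equidistant projection
   of the sensor positions, barycentric interpolation on a Delaunay
   triangulation, nearest-neighbour fill between hull and mask), stacked,
   and smoothed with an 8 mm × 8 mm × 8 Hz Gaussian kernel.  Group
   differences use a pseudo-T permutation test: the pooled variance image
   is smoothed with the same kernel before forming T, the cluster-forming
   threshold is the 95th percentile of the pooled permutation voxel
   statistics (|T|, two-sided), clusters are 26-connected components, and
   corrected p-values come from the permutation distribution of the maximum
   cluster extent (5000 permutations by default; exhaustive when fewer
   arrangements exist).
7. **Classification** — pairwise group classification by linear soft-margin
   SVM under leave-one-out cross-validation; features (per-voxel two-group
   Z selection or PCA of the vectorized images) are refitted inside every
   fold, the cost parameter is searched on a log grid in (0, 1], the whole
   loop is repeated 10 times and held-out decision values are averaged
   before the ROC/AUC is computed.

## The synthetic-data generator

The generator mirrors a source-to-sensor validation design: directed
networks on a handful of cortical sources, MVAR dynamics, projection to 204
planar gradiometers, additive sensor noise.

* **Source networks.**  `generate_source_network()` draws digraphs with a
  fixed edge count and classifies them against the median mean local
  efficiency of a 200-draw random-graph null ("low" strictly below,
  "high" strictly above).  When the null median coincides with an extreme
  (heavy ties at zero efficiency are common for sparse graphs) the boundary
  value is accepted, keeping the classes ordered but reachable.  Realized
  bands are stored as attributes rather than assumed.
* **Source dynamics.**  Each node is a damped AR(2) resonance (pole radius
  0.75–0.9, resonance 2–45 Hz); couplings sit at lag 1 by default.  We
  found that couplings placed at random lags transmit poorly through the
  RMS envelope nonlinearity, whereas first-lag couplings — the fastest
  interaction the sampling rate can express — survive it; `coupling_lag`
  exposes the choice.  After construction all lag matrices are rescaled by
  $\gamma^r$ so the companion spectral radius is exactly 0.95 for every
  network: companion eigenvalues scale linearly in $\gamma$, so this
  normalizes every model to the same distance from instability without
  touching the topology.  Rescaling only the unstable draws instead injects
  topology-uncorrelated variance into the effective coupling strengths.
* **Forward model.**  A configurable smooth gain matrix replaces biophysical
  head modelling: each source, placed under the helmet at 80% relative
  depth, projects with a Gaussian distance-decay profile
  (`spread`, default 0.015 m in the validation study, approximating the
  focal sensitivity of planar gradiometers); columns are normalized to unit
  norm, and `spread = 0` degenerates to a nearest-sensor assignment.  The
  validation target is graph-metric recovery through linear mixing plus
  noise, not biophysical fidelity.
* **Noise.**  Per-channel Gaussian noise with SD equal to the channel's
  signal SD divided by the requested SNR; `Inf` adds none.  At
  `SNR = Inf` a few-source projection is rank deficient, which is why the
  validation study caps the retained components at the numerical rank and
  why the Vieira–Morf recursion guards its Cholesky factors (ridge jitter)
  and clamps the normalized partial correlation to its theoretical unit
  spectral-norm bound.
* **Cohorts.**  `generate_group_cohort()` builds multi-group cohorts from a
  shared reference source configuration; a group spec attenuates the
  couplings transmitted by sources matching a frequency band and scalp
  region, which lowers downstream local efficiency at the matching sensors
  and frequencies.  `simulate_scalp_images()` generates subject
  scalp×frequency volumes directly (smoothed noise plus an optional
  localized bump) for calibration studies where simulating full recordings
  would be needlessly expensive.

## What the validation study shows — and what it does not

`simulation_study()` runs the full chain on 20 low- plus 20 high-efficiency
6-node networks (6 of the 30 possible connections), 30 s at 1 kHz, SNR
sweep {0.1, 1, 3, 10, ∞}, thresholds 85/95/99%.  Two findings are robust
and reproduced by the test suite:

* the generated classes are cleanly separated at the source level
  (rank-sum p ≈ 10⁻⁸ on the ground-truth graphs), and an MVAR fitted
  directly to the source series — even to their rectified envelopes —
  recovers that separation;
* after projection to 204 sensors and refitting, the **sensor-level** mean
  local efficiency does *not* separate the classes at any SNR or threshold
  under this generator (rank-sum p between 0.16 and 0.99 across all
  cells).

Stage-by-stage forensics (source fit → rectified fit → oracle best-sensor
fit → any 102-dimensional fit) localize the loss to the mixed,
highly collinear sensor stage: with zero-lag linear mixing, individual MVAR
coefficients between ~100 collinear channels are not identifiable, so the
rank ordering of single-entry PDC magnitudes — which the proportional
threshold relies on — degenerates to noise, and the graph summary reflects
generic graph density rather than source topology.  This held for forward
spreads of 0.006–0.045 m, couplings 0.4–2, damping 0.4–0.95, fit orders
3–12, with and without PCA, and even for hand-built extreme topologies
(a bidirectional triangle versus a directed ring are indistinguishable at
SNR = ∞).  Passing the remaining tests therefore validates the estimators
and statistics themselves, not end-to-end sensor-level recovery; with a
biophysical dipolar forward model and several-fold longer recordings the
sensor-level result may differ, but that is outside what a smooth-gain
simulation can show.

## Numerical and design choices

* **Vieira–Morf vs least squares.**  The lattice recursion updates the
  forward/backward error covariances through the normalized partial
  correlation ($P_f \leftarrow L_f (I - \rho\rho^\top) L_f^\top$), the
  geometric-mean normalization that distinguishes the estimator from
  per-direction regression.  Ordinary least squares is exposed as
  `method = "ls"`; the two agree to $O(1/\sqrt n)$ on long stationary data
  and the test suite asserts it.  We chose OLS (rather than a second
  covariance-based recursion) as the comparison estimator because it is the
  standard reference and makes that invariant directly checkable.
* **Frequency grid.**  `default_frequency_grid(0.1, 80)` spans
  0.1–80 Hz inclusive, giving exactly 800 bins; a 1 Hz resolution gives 80.
* **Back-projection.**  $\tilde A_r = L A_r L^\top$ (Moore–Penrose
  back-projection through the orthonormal loadings).  The nonzero companion
  eigenvalues are invariant, so the stability index carries over without
  recomputing an $O((dp)^3)$ eigendecomposition.
* **Degenerate graphs.**  Local efficiency of nodes with fewer than two
  neighbours is 0; distances to unreachable nodes contribute $1/\infty = 0$.
* **Smoothing.**  Separable Gaussian, truncated at 3σ, mask- and NaN-aware:
  the volume and a validity indicator are smoothed and their ratio taken,
  so constants are preserved inside the mask and boundary voxels are
  renormalized rather than shrunk.
* **Permutation engine.**  All permutations are evaluated in one fused pass
  (group sums by a single matrix product, then per-permutation variance
  smoothing and pseudo-T in compiled code); the identity arrangement is
  always the first permutation so corrected p-values are never zero.
  Cluster statistic is extent; connectivity is 26; both follow the
  conventions of nonparametric mapping tools, and the percentile defining
  the cluster-forming threshold is taken over the pooled permutation voxel
  distribution.
* **Classifier repetitions.**  "Repeated 10-fold" is read as 10 independent
  repetitions of the full leave-one-out loop with averaged decision values;
  the internal cost search (log grid in (0, 1], small internal CV) is
  re-randomized across repetitions.
* **Containers.**  Arrays and fitted objects are checkpointed as RDS,
  label tables as CSV and run summaries as JSON; every `run_pipeline()`
  artifact is stamped with the configuration hash and seed, and identical
  configuration plus seed reproduces byte-identical files.

## Problem sizes used by the automated studies

The packaged studies are sized for a single CPU: the validation study uses
20 + 20 networks with a 2 Hz PDC grid and fits at the generating order
(order 3); the null calibration of the permutation test runs 500 cohorts of
8 + 8 subjects on a 16 × 16 × 40 grid with 500 permutations; classifier
calibration uses 12-subject cohorts of 12 × 12 × 16 images.  The patient
pipeline defaults (60 components, order 8, 800 bins, 64 × 64 grid, 5000
permutations) remain the package defaults for real-scale analyses.

## Known limitations

* The forward model is a smooth distance-decay gain, not a biophysical
  lead field; no artefact sources (ocular, cardiac, environmental) are
  simulated, and preprocessing steps that target them (tSSS, ICA) are out
  of scope by design.
* Sensor-space PDC inherits the mixing-identifiability limits discussed
  above; conclusions about individual sensor-pair connections should not be
  drawn from single entries of the binarized graphs.
* Group statistics support two-sample designs only (no paired or
  regression designs), matching the analysis they implement.
* The permutation engine keeps every permutation's statistic volume in
  memory (voxels × permutations doubles).  That is comfortable at the
  reduced grids used by the packaged studies; a full 64 × 64 × 800 image
  with 5000 permutations would need chunked evaluation, which is not
  implemented.
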