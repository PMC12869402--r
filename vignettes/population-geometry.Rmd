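---
title: "Population geometry of neural responses: models, metrics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population geometry of neural responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurogeom)
```

## The problem

A population of visual neurons (biological or artificial) responds to a
parametric stimulus ensemble — drifting gratings and optical-flow
patterns moving in each of several directions — and the responses are
summarized as peristimulus time histograms (PSTHs): a nonnegative tensor
of neurons × stimulus sequences × time bins. `neurogeom` asks three
complementary questions of such a tensor:

1. **Decoding.** How are *stimuli* arranged in the space of population
   activity? PCA of time-averaged activity gives a *decoding manifold*
   (one point per stimulus condition); treating each time step as its
   own point gives *decoding trajectories* that trace the population
   state over the trial.
2. **Encoding.** How are *neurons* arranged in the space of
   stimulus-response patterns? Nonnegative tensor factorization,
   an adaptive similarity graph, and a diffusion-map embedding give an
   *encoding manifold* in which nearby neurons respond similarly to
   similar stimuli. Its topology distinguishes clustered (retina-like)
   from continuous (cortex-like) functional organization.
3. **Dynamics.** Do same-stimulus trajectories form tight, separated
   "tubes", and how often do trajectories from different stimuli
   exchange order? Two *tubularity* scores — tightness and crossings —
   quantify this, with a bootstrap test for comparing two systems.

A four-metric battery (RSA, CCA, linear predictivity, DSA) scores
representational alignment between any two systems that saw the same
ensemble. Because real recordings and large pretrained networks are out
of reach for automated validation, a synthetic module generates
populations and trajectory bundles with planted ground truth; every
stage of the package is exercised against those constructions.

## The stimulus ensemble

The default ensemble has 6 base classes — one square-wave grating class
carrying six spatial-frequency variants, plus five optical-flow patterns
with one variant each — each variant drifting in 8 directions on a
45-degree grid: 11 variants × 8 directions = 88 unique sequences.
Averaging variants within a class leaves 6 × 8 = 48 class-direction
analysis units, the default grouping for manifolds, trajectories and
classification. This composition is one simple factorization consistent
with all four design counts (88, 48, 8, 6); the class/variant layout is
fully configurable when a different split is wanted.

Directions are degrees, counter-clockwise, 0 = rightward drift. Time
bins are uniform; bin centers start at `binWidth/2` after stimulus
onset (no pre-stimulus period). PSTH binning and normalization are
exposed as configuration (`binWidth`, `nTimeBins`, and the encoding
tensor's `normalization`) rather than fixed, since no single convention
suits every source of data.

## The response simulator

`simulatePopulation()` draws, per neuron, a planted class, a preferred
direction (uniform on the circle), a von Mises concentration kappa, a
gain, and a temporal profile, and builds the separable response

    rate(neuron, sequence, t) =
      gain × classAffinity(class) × exp(kappa (cos(direction − preferred) − 1))
           × profile(t)

plus noise, clipped at zero. Class affinity is 1 for the planted class
and `offClassGain` (default 0.15) otherwise. The profiles are a
transient gamma-shaped pulse, a saturating ramp ("sustained"), a
rectified sinusoid at the stimulus temporal frequency ("periodic"), a
linear ramp, and a *nonselective* mode for intensity-arm units: equal
affinity to every class and direction with activity that builds up over
the first time steps and then sustains. Noise is either truncated
Gaussian (constant scale) or Poisson-like (variance proportional to the
mean). Spatial-frequency variants share their class's response by
default, so variant averaging is exact rather than approximate.

Defaults — 20 tuned neurons per class plus 12 nonselective units, kappa
in [2, 6], gains in [0.8, 1.2], Gaussian noise at 0.05 of peak rate, 20
bins of 50 ms (1 s trials, 2 Hz periodic stimuli) — are sized so that a
default run is a desk-scale but non-trivial population: classification
is high but imperfect, and manifolds show visible class structure over
noise. Two switches create *typed* populations for recovery
experiments: `sharedTuning` gives every neuron of a class the same
(preferred direction, kappa) pair, and `profilesByClass` fixes one
profile per class. With both set, `offClassGain = 0` and zero noise, a
class is a set of exactly proportional neurons — the idealized
"retina-like" regime in which the encoding pipeline must recover the
planted classes perfectly.

What the simulator does *not* emulate: trial-to-trial variability
(the tensor is trial-averaged by construction), correlated noise across
neurons, adaptation or cross-orientation suppression, and any actual
image computation — stimuli exist only as labels. Passing tests
therefore show that the geometry pipeline recovers structure *of the
kind planted*, not that it handles every pathology of real recordings.

## Decoding manifolds and trajectories

Both constructions use unscaled PCA (grand-mean centering, no
per-neuron variance scaling): activity magnitude is meaningful here —
the nonselective "intensity" dimension the encoding analysis isolates
would be destroyed by z-scoring. The manifold PCA is fit on the 48
time-averaged unit vectors; the trajectory PCA is fit on the pooled
(unit, time) cloud, so the two live in related but distinct spaces, and
each object carries its own projection (center and rotation). Because
projections are linear, the time average of a trajectory equals the
time-averaged unit mapped through the trajectory projection — an
identity the tests assert to 1e-8.

Classification accuracy defaults to leave-one-unit-out nearest class
centroid (Euclidean, ties to the lowest class index); a stratified
k-fold ridge classifier on class indicators is the alternative. Both
operate on the same time-averaged unit vectors as the manifold, and the
labels argument allows shuffle controls. Orientation- and
direction-selectivity indices use the circular-variance (vector-sum)
convention, `|Σ r e^{iθ}|/Σ r` with doubled angles for OSI; it is
bounded in [0, 1], needs no null-direction choice, and handles the
all-zero neuron by returning 0.

`ablateNeurons()` removes a named neuron set so any downstream object
can be recomputed on the complement — the operation behind the
intensity-arm analysis, where removing nonselective units collapses the
shared temporal development of all trajectories.

## The encoding pipeline

The encoding tensor is neurons × conditions × time, normalized per
neuron to peak 1 so the factorization reflects response *shape*;
all-zero neurons are flagged and excluded. Nonnegative CP decomposition
is computed by hierarchical alternating least squares (HALS): each
factor column update is an exact nonnegative coordinate minimizer, so
the Frobenius objective is non-increasing (asserted per run on the
recorded trace). The best of several seeded random restarts is kept.
Rank defaults to an elbow rule — the smallest rank whose relative-error
improvement over the previous rank falls below 5% — and can be fixed.

Neuron similarity uses a Gaussian kernel with local scales on
L2-normalized factor rows: `A_ij = exp(−d_ij² / (σ_i σ_j))` with
`σ_i` the distance to the i-th row's k-th neighbor. This
adaptive-bandwidth kernel is a fully specified stand-in for
adaptive-neighborhood constructions whose details vary between
pipelines; duplicates (σ = 0) are floored at a machine-scaled epsilon
and reported. The diffusion map row-normalizes the affinity to a Markov
matrix, removes the trivial constant eigenvector by deflation, and
embeds with the top nontrivial right eigenvectors scaled by
`λ^diffusionTime` (default 1). Three conventions make it deterministic
and well behaved: eigenvector columns are unit-normalized (invariance
to affinity rescaling), each column's largest-magnitude entry is made
positive (sign convention), and for disconnected graphs the
unit-eigenvalue indicator directions are retained, so components
separate in the leading coordinates and are also reported as labels.
When the spectrum has fewer positive nontrivial eigenvalues than
requested dimensions (e.g. exact duplicate blocks), the embedding
shrinks with a warning rather than failing.

`topologyStats()` summarizes whether the manifold is clustered or
continuous: connected components of a k-nearest-neighbor graph, a
cluster-gap ratio (mean nearest-neighbor distance between k-means
clusters over mean within-cluster nearest-neighbor distance, with k
chosen by mean silhouette width), and the adjusted Rand index against
planted labels when available. Full-pipeline permutation equivariance
holds at the graph and embedding stages exactly; the HALS stage is
equivariant in distribution only, because its random initialization is
seeded independently of neuron order.

## Tubularity

For labeled trajectory bundles, per time step and class, `w_c(t)` is
the mean distance of class-c points to their class centroid, and
`b(t)` the mean pairwise distance between class centroids. The
tightness of class c is the time average of `b/(b + 2 w_c)` and the
pooled score is the trajectory-count-weighted mean of class scores:
dimensionless, in [0, 1], equal to 1 exactly when dispersion vanishes
against separated centroids, 0 when centroids coincide, and 0.5 when
centroid spacing equals twice the within-bundle spread (tubes
touching; the factor 2 is configurable in spirit — it is a definition,
not a fit). Averaging per-class scores rather than pooling `w` first
makes the per-class breakdown average *exactly* to the pooled score;
the two conventions coincide whenever class dispersions are equal.

The crossings score counts order exchanges: for every cross-class
trajectory pair, both trajectories are projected onto the axis joining
the two class centroids at each time step, and a crossing event is a
sign flip of the projected difference between consecutive steps. The
axis is *oriented continuously in time* (each step's unit vector is
sign-aligned with the previous step's). This matters: when two bundles
pass through each other, the raw inter-centroid difference reverses
direction at the crossing, which would silently cancel the very event
being counted; the continuous orientation counts it once, makes an
X-configuration of straight bundles score exactly `1/(T−1)` (one
exchange per pair over `T−1` steps, verified against a brute-force
segment-intersection oracle), and makes time-reversal symmetry exact.
Events per cross-class pair per step normalizes the score into [0, 1].
Both scores use plain Euclidean distances in whatever space the
trajectories are given in (by default the decoding-trajectory PCA
space), and both are invariant to rotation, translation and uniform
scaling. A crossing that lands *exactly* on a sampled time step (zero
projected difference at that sample) is not counted — a measure-zero
event for dispersed bundles.

An alternative reading of "crossings" — geometric intersection counts
of trajectory polylines — coincides with the order-exchange definition
on the constructed bundles used for validation; which of the two (or a
bundle-membership-switch variant) best matches usage elsewhere cannot
be settled from descriptions alone, so the definition here is versioned
by its tests.

`compareScores()` compares a metric between two systems with a
studentized bootstrap: trajectories are resampled with replacement
within class in each set, the bootstrap standard error of
`delta = metric(A) − metric(B)` is estimated from the replicates, and
`delta/SE` is referred to the standard normal, floored at
`1/(nBoot+1)`. The studentized form was chosen over the raw
percentile-tail form because the latter is conservative at these
per-class sample sizes (empirical size ~0.015 at nominal 0.05 in the
200-replication null calibration the tests run; the studentized form
sits at ~0.04). `delta = 0` returns p = 1 by convention. Bonferroni
correction multiplies by the caller's number of comparisons, capped at
1.

## The alignment battery

* **RSA** — each system's representational dissimilarity matrix is the
  correlation distance (1 − Pearson across features) between condition
  rows; the score is the Spearman correlation of the two upper
  triangles. Conditions with zero feature variance are dropped from
  both sides and reported.
* **CCA** — each side is reduced to `pcaDim` principal components (the
  guard against rank-deficient feature spaces), then the mean of the
  top `nComponents` canonical correlations. With `pcaDim` at least the
  data rank, any invertible linear map of one side scores exactly 1.
* **Linear predictivity** — k-fold cross-validated ridge regression
  from one system to the other; the score is the mean over target
  features of the Pearson correlation between pooled out-of-fold
  predictions and truth. It is directional, so the report computes both
  directions and stores their mean. Note that with more source
  features than conditions, even identical systems score below 1: the
  cross-validated map is not identified. The ridge solve is the exact
  closed form at a fixed penalty.
* **DSA** — each system's pooled trajectory points are reduced to
  `rank` principal components and a one-step linear operator A is
  fitted by least squares over within-trajectory transitions; the
  dissimilarity is `min_Q ‖A_X − Q A_Y Qᵀ‖_F / max(‖A_X‖_F, ‖A_Y‖_F)`
  over orthogonal Q, and the score is 1 minus the capped dissimilarity.
  The minimization runs BFGS over a Cayley parameterization of
  rotations from multiple starts — identity, all diagonal sign matrices
  (covering PCA sign ambiguity and the reflection component of the
  orthogonal group) and seeded random orthogonal starts. No delay
  embedding is applied beyond the PCA reduction; restarts default
  to 10.

The report's `mean_score` is the plain arithmetic mean of the four
scores — they live on different natural scales, but an unweighted mean
is the only aggregation the battery's definition supports, and the
per-metric values are always stored alongside it.

## The pipeline driver

`runPipeline(config)` runs the full synthetic study from one YAML file:
simulate two populations on a shared ensemble, write the tensors as CSV
bundles with their ground truth, build the decoding manifold and
trajectories, classification accuracy and selectivity, the encoding
manifold and its topology summary, tubularity with a bootstrap
comparison between the two systems, and the alignment report. Every
stage seed derives deterministically from the single global seed
(global seed mod 1e6, times 1000, plus a fixed per-stage offset); the
run log echoes every seed and parameter, and `manifest.json` records
each completed stage and its files, so a partial failure still
documents what finished. Unknown configuration keys fail fast with the
key named. Interchange formats are plain text throughout — CSV bundles
(activity written with 17 significant digits, so read/write round
trips are value-exact), CSV coordinate tables, JSON reports.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at desk scale, chosen
as the smallest sizes at which each property is cleanly exhibited:
populations of roughly 60–130 neurons over the 88-sequence ensemble,
bundles of 2–3 classes with 5–8 trajectories over 10–20 steps, 200
replications for test-size calibration (nBoot = 500), and 100
replications for the DSA discrimination experiment. Tolerances follow
the quantity: exact identities (PCA projection consistency, round
trips) are asserted at 1e-8 or tighter; recovery cosines at 0.999 for
exact-rank inputs; stochastic rates with explicit bands. Degenerate
inputs are handled by stated conventions rather than errors wherever a
convention is defensible (all-zero neurons flagged, zero-response
selectivity 0, coincident centroids score 0, ties broken toward the
first index); genuinely ill-posed requests (too few classes, rank
beyond the spectrum, ablating every neuron) fail with named errors.

## Known limitations

* The tensor is trial-averaged; nothing here models single-trial
  decoding or noise correlations.
* HALS is a local optimizer: factor recovery guarantees extend only to
  well-separated planted structure, and the rank elbow rule is a
  heuristic.
* The tubularity scores ignore curvature; they summarize dispersion
  and order exchanges only.
* DSA compares *linear* one-step operators; systems with matching
  linear parts but different nonlinearities will look more similar than
  they are.
* The adaptive-kernel and diffusion conventions here are one concrete,
  tested choice among several in circulation; coordinates are
  comparable within this package, not across toolkits.
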