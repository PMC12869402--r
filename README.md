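# neurogeom

Population-geometry analysis of neural responses to parametric visual
stimuli, for computational neuroscientists comparing biological
recordings with artificial network activity. Starting from a
stimulus-response tensor — nonnegative activity of N neurons to S
stimulus sequences over T time bins (PSTHs) — the package builds:

* **Decoding manifolds**: PCA of time-averaged population activity, one
  point per stimulus condition, revealing how well the stimulus can be
  read off the population state.
* **Decoding trajectories**: the same PCA idea with each time step as
  its own point, tracing population dynamics through the trial.
* **Encoding manifolds**: each *neuron* embedded in stimulus-response
  space via nonnegative CP tensor factorization (HALS), an
  adaptive-bandwidth Gaussian similarity graph, and a diffusion-map
  embedding — nearby neurons respond similarly to similar stimuli, and
  topology statistics quantify clustered (retina-like) versus
  continuous (cortex-like) organization.
* **Tubularity scores** for labeled trajectory bundles: tightness
  `S_tight = mean_t b/(b + 2w)` (between-centroid spacing `b` against
  within-bundle dispersion `w`, in [0, 1]) and crossings `S_cross`
  (order exchanges per cross-class trajectory pair per time step, on a
  continuously oriented inter-centroid axis), with a studentized
  bootstrap test for comparing two systems and Bonferroni correction.
* **Representational alignment**: RSA (Spearman correlation of
  correlation-distance RDMs), CCA after PCA reduction, cross-validated
  ridge linear predictivity (both directions), and DSA (fitted one-step
  linear operators compared up to an orthogonal change of basis), plus
  their arithmetic mean.

A synthetic-data module generates the study conditions end to end: an
88-sequence ensemble (6 stimulus classes, 11 variants, 8 drift
directions), direction-tuned populations with von Mises tuning,
separable gain × tuning × temporal-profile responses, planted classes
and profiles, and geometric trajectory bundles with known crossing
structure — so every stage is testable without any external data.

## Worked example

```r
library(neurogeom)

ens <- makeStimulusEnsemble()           # default ensemble
ens
#> StimulusEnsemble: 88 sequences, 6 classes x 11 variants x 8 directions
#>   classes: grating, onedot_flow, threedot_flow, dense_flow, radial_flow, rotational_flow

sim <- simulatePopulation(ens, seed = 1)
sim$tensor
#> ResponseTensor: 132 neurons x 88 sequences x 20 time bins (0.05 s bins)
#>   activity range [0, 1.255]

mf <- buildDecodingManifold(sim$tensor, nDims = 3)
mf
#> DecodingManifold: 48 points in 3 dims
#>   explained variance: 0.136 0.088 0.069

classificationAccuracy(sim$tensor)
#> [1] 0.9375

trajs <- buildDecodingTrajectories(sim$tensor, nDims = 3)
tubularityScores(trajs)
#> TubularityScores: S_tight = 0.1744, S_cross = 0.1039
#>   per-class tightness: dense_flow=0.138, grating=0.166, onedot_flow=0.180, radial_flow=0.180, rotational_flow=0.197, threedot_flow=0.185
```

Reading the numbers: the 88 sequences collapse to 48 class-direction
points after variant averaging; leave-one-out nearest-centroid
classification reads the stimulus class off time-averaged population
activity 94% of the time at the default noise level; the low tightness
(0.17) with a nonzero crossing rate (0.10) says this default
population's trajectories form loose, partially interleaved bundles —
raise tuning sharpness or cut noise and `S_tight` rises toward 1.

The encoding side, on a typed ("retina-like") population:

```r
em <- buildEncodingManifold(sim$tensor, rank = "auto", nDims = 3, seed = 1)
topologyStats(em, labels = sim$groundTruth$planted_class[
  match(neuronIds(em), sim$groundTruth$neuron_id)])
```

and the full synthetic study — simulate two systems, decode, encode,
score tubularity, run the alignment battery, write CSV/JSON artifacts
with a manifest and seed log — runs from one YAML file:

```r
runPipeline(system.file("extdata", "demo_config.yaml",
                        package = "neurogeom"),
            outputDir = "demo_run")
```

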