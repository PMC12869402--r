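Package: neurogeom
Title: Population Geometry of Neural Responses: Manifolds, Trajectory
    Tubularity, and Representational Alignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for interpreting neural population activity through its
    geometry. Builds decoding manifolds and decoding trajectories from
    stimulus-response tensors (PCA on time-averaged and time-resolved
    population activity), encoding manifolds of neurons via nonnegative
    tensor factorization, adaptive-kernel similarity graphs and diffusion
    embeddings, and quantifies trajectory-bundle geometry with tightness
    and crossings (tubularity) scores, including a bootstrap comparison
    test. A representational-alignment battery (RSA, CCA, linear
    predictivity, dynamical similarity analysis) scores agreement between
    two systems responding to a shared stimulus ensemble. A synthetic-data
    module generates direction-tuned, temporally structured population
    responses and geometric trajectory bundles with planted ground truth,
    so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    cluster,
    mclust,
    igraph,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
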