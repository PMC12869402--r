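test_that("the default synthetic study yields a 48-point decoding manifold", {
  ens <- makeStimulusEnsemble()
  sim <- simulatePopulation(ens, list(nPerClass = 5L, nNonselective = 3L),
                            seed = 1L)
  mf <- buildDecodingManifold(sim$tensor, nDims = 3L)
  expect_equal(nrow(coords(mf)), 48L)
  expect_equal(nrow(pointLabels(mf)), 48L)
  mfSeq <- buildDecodingManifold(sim$tensor, nDims = 3L,
                                 grouping = "sequence")
  expect_equal(nrow(coords(mfSeq)), 88L)
  evr <- explainedVariance(mf)
  expect_true(all(diff(evr) <= 1e-9))
  expect_lte(sum(evr), 1 + 1e-9)
  expect_error(buildDecodingManifold(sim$tensor, nDims = 500L),
               "dimension error")
})

test_that("identical responses for all sequences collapse to the origin", {
  ens <- tinyEnsemble(2L)
  a <- array(0.7, dim = c(4, 16, 5))
  mf <- buildDecodingManifold(tensorFrom(a, ens), nDims = 2L)
  expect_true(all(abs(coords(mf)) < 1e-10))
})

test_that("disjoint class populations produce a cleanly separated manifold", {
  ens <- tinyEnsemble(2L)
  sim <- simulatePopulation(ens, list(nPerClass = 10L, nNonselective = 0L,
                                      offClassGain = 0, noiseScale = 0,
                                      sharedTuning = TRUE,
                                      kappaRange = c(0.1, 0.1)),
                            seed = 2L)
  mf <- buildDecodingManifold(sim$tensor, nDims = 3L)
  sil <- bruteSilhouette(coords(mf), pointLabels(mf)$base_class)
  expect_gt(sil, 0.9)
})

test_that("manifold coordinates are neuron-permutation invariant up to sign", {
  ens <- tinyEnsemble(2L)
  sim <- simulatePopulation(ens, list(nPerClass = 6L, nNonselective = 2L),
                            seed = 3L)
  t1 <- sim$tensor
  set.seed(8); perm <- sample(length(neuronIds(t1)))
  t2 <- ResponseTensor(activity(t1)[perm, , ], binWidth(t1), ensemble(t1),
                       neuronIds(t1)[perm])
  c1 <- coords(buildDecodingManifold(t1, nDims = 3L))
  c2 <- coords(buildDecodingManifold(t2, nDims = 3L))
  for (d in 1:3)
    expect_true(max(abs(c1[, d] - c2[, d])) < 1e-8 ||
                  max(abs(c1[, d] + c2[, d])) < 1e-8)
})

test_that("temporally constant activity collapses trajectories to points", {
  ens <- tinyEnsemble(2L)
  set.seed(4)
  base <- matrix(runif(3 * 16), 3, 16)
  a <- array(base, dim = c(3, 16, 6))       # same value at every time bin
  tr <- trajectories(buildDecodingTrajectories(tensorFrom(a, ens), nDims = 2L))
  for (k in seq_len(dim(tr)[1]))
    expect_lt(max(abs(sweep(tr[k, , ], 2L, tr[k, 1, ]))), 1e-10)
})

test_that("periodic responses with integer cycles close their loops", {
  ens <- tinyEnsemble(2L)
  sim <- simulatePopulation(ens, list(
    nPerClass = 8L, nNonselective = 0L, noiseScale = 0,
    profilesByClass = list(A = "periodic", B = "periodic"),
    temporalFreq = 2, nTimeBins = 20L, binWidth = 0.05), seed = 5L)
  trs <- buildDecodingTrajectories(sim$tensor, nDims = 3L)
  tr <- trajectories(trs)
  period <- 10L                             # 2 Hz at 0.05 s bins
  for (k in seq_len(dim(tr)[1])) {
    diam <- max(dist(tr[k, , ]))
    gap <- sqrt(sum((tr[k, 1, ] - tr[k, 1 + period, ])^2))
    if (diam > 0) expect_lt(gap, 1e-6 * diam)
  }
})

test_that("full-rank trajectory PCA reconstructs the centered data", {
  ens <- tinyEnsemble(2L)
  set.seed(6)
  a <- array(runif(5 * 16 * 4), dim = c(5, 16, 4))
  tensor <- tensorFrom(a, ens)
  trs <- buildDecodingTrajectories(tensor, nDims = 5L, grouping = "sequence")
  pr <- projection(trs)
  pooled <- matrix(aperm(array(aperm(trajectories(trs), c(2, 1, 3)),
                               dim = c(16 * 4, 5)), c(1, 2)), ncol = 5)
  recon <- pooled %*% t(pr$rotation)
  orig <- matrix(aperm(a, c(3, 2, 1)), ncol = 5)   # (t fastest, then seq)
  origCentered <- sweep(orig, 2L, pr$center)
  relErr <- max(abs(recon - origCentered)) / max(abs(origCentered))
  expect_lt(relErr, 1e-8)
})

test_that("a manifold point is the time average of its trajectory", {
  ens <- tinyEnsemble(3L)
  sim <- simulatePopulation(ens, list(nPerClass = 5L, nNonselective = 2L),
                            seed = 7L)
  trs <- buildDecodingTrajectories(sim$tensor, nDims = 4L)
  pr <- projection(trs)
  X <- conditionResponses(sim$tensor)       # time-averaged units x neurons
  mapped <- sweep(X, 2L, pr$center) %*% pr$rotation
  tr <- trajectories(trs)
  avg <- t(vapply(seq_len(dim(tr)[1]), function(k) colMeans(tr[k, , ]),
                  numeric(dim(tr)[3])))
  expect_lt(max(abs(mapped - avg)), 1e-8)
})

test_that("noiseless separable classes classify perfectly; zeros fall to prior", {
  ens <- makeStimulusEnsemble()
  sim <- simulatePopulation(ens, list(nPerClass = 4L, nNonselective = 0L,
                                      offClassGain = 0, noiseScale = 0,
                                      sharedTuning = TRUE,
                                      kappaRange = c(0.5, 0.5)),
                            seed = 8L)
  expect_equal(classificationAccuracy(sim$tensor), 1.0)
  expect_equal(classificationAccuracy(sim$tensor, scheme = "linear-cv",
                                      seed = 1L), 1.0)
  # all-zero activity: ties broken toward the first class -> <= max prior
  z <- tensorFrom(array(0, dim = c(3, 88, 4)), ens)
  accZ <- classificationAccuracy(z)
  expect_lte(accZ, max(table(pointLabels(
    buildDecodingManifold(z, 1L))$base_class)) / 48)
})

test_that("shuffled labels drop accuracy to the binomial chance band", {
  ens <- makeStimulusEnsemble()
  sim <- simulatePopulation(ens, list(nPerClass = 4L, nNonselective = 0L,
                                      offClassGain = 0, noiseScale = 0),
                            seed = 9L)
  units <- pointLabels(buildDecodingManifold(sim$tensor, 2L))
  accs <- vapply(1:10, function(s) {
    set.seed(100 + s)
    classificationAccuracy(sim$tensor, labels = sample(units$base_class))
  }, numeric(1))
  p <- 1 / 6
  band <- 3 * sqrt(p * (1 - p) / 48)   # binomial null, one shuffle
  expect_lt(abs(mean(accs) - p), band)
})

test_that("degenerate single-unit classes are rejected under leave-one-out", {
  ens <- tinyEnsemble(2L)
  sim <- simulatePopulation(ens, list(nPerClass = 3L, nNonselective = 0L),
                            seed = 10L)
  units <- pointLabels(buildDecodingManifold(sim$tensor, 2L))
  lab <- units$base_class
  lab[lab == "B"] <- "A"; lab[1] <- "B"     # leave class B with one unit
  expect_error(classificationAccuracy(sim$tensor, labels = lab),
               "degenerate-class")
})

test_that("selectivity indices follow the vector-sum convention exactly", {
  ens <- tinyEnsemble(1L)
  mk <- function(r) {                       # r: response per direction
    a <- array(rep(r, each = 1), dim = c(1, 8, 2))
    tensorFrom(a, ens)
  }
  flat <- selectivityIndices(mk(rep(1, 8)))
  expect_equal(flat$dsi, 0); expect_equal(flat$osi, 0)
  single <- selectivityIndices(mk(c(1, rep(0, 7))))
  expect_equal(single$dsi, 1); expect_equal(single$osi, 1)
  opposed <- selectivityIndices(mk(c(1, 0, 0, 0, 1, 0, 0, 0)))
  expect_equal(opposed$dsi, 0)
  expect_equal(opposed$osi, 1)
  zero <- selectivityIndices(mk(rep(0, 8)))
  expect_equal(zero$dsi, 0); expect_equal(zero$osi, 0)
})

test_that("ablation removes exactly the requested neurons", {
  ens <- tinyEnsemble(2L)
  sim <- simulatePopulation(ens, list(nPerClass = 4L, nNonselective = 2L),
                            seed = 11L)
  t0 <- sim$tensor
  same <- ablateNeurons(t0, character(0))
  expect_identical(activity(same), activity(t0))
  drop2 <- ablateNeurons(t0, neuronIds(t0)[1:2])
  expect_equal(length(neuronIds(drop2)), length(neuronIds(t0)) - 2L)
  expect_error(ablateNeurons(t0, "ghost"), "lookup error")
  expect_error(ablateNeurons(t0, neuronIds(t0)), "validation error")
})

test_that("ablating the intensity arm removes the temporal development", {
  # selective units are temporally stationary; all temporal variance is
  # carried by the nonselective (intensity) units
  ens <- tinyEnsemble(2L)
  sq <- sequenceTable(ens); S <- nrow(sq); T <- 12L
  nSel <- 8L; nInt <- 4L
  set.seed(12)
  a <- array(0, dim = c(nSel + nInt, S, T))
  for (n in seq_len(nSel)) {
    pref <- ifelse(n <= 4, "A", "B")
    tuning <- ifelse(sq$base_class == pref, 1, 0.1) *
      exp(2 * (cos((sq$direction - 45 * n) * pi / 180) - 1))
    a[n, , ] <- matrix(tuning, S, T)        # constant in time
  }
  ramp <- seq(0, 1, length.out = T)
  for (n in nSel + seq_len(nInt)) a[n, , ] <- outer(rep(1, S), 3 * ramp)
  tensor <- tensorFrom(a, ens)
  full <- buildDecodingTrajectories(tensor, nDims = 3L)
  ablated <- buildDecodingTrajectories(
    ablateNeurons(tensor, sprintf("u%02d", nSel + seq_len(nInt))), nDims = 3L)
  expect_lt(meanPathLength(ablated), 0.5 * meanPathLength(full))
})
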