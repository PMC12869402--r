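test_that("per-neuron-max normalization scales slabs to peak 1 and flags zeros", {
  ens <- tinyEnsemble(1L)
  set.seed(1)
  a <- array(runif(4 * 8 * 5), dim = c(4, 8, 5))
  a[3, , ] <- 0
  et <- encodingTensor(tensorFrom(a, ens))
  expect_equal(et$zeroNeurons, "u03")
  for (n in c(1, 2, 4)) expect_equal(max(et$values[n, , ]), 1)
  expect_true(all(et$values[3, , ] == 0))
  raw <- encodingTensor(tensorFrom(a, ens), normalization = "none")
  expect_identical(raw$values, a)
})

test_that("HALS recovers an exact rank-1 tensor to machine precision", {
  set.seed(21)
  u <- runif(12); v <- runif(9); w <- runif(7)
  x <- outer(outer(u, v), w)
  fit <- ntfDecompose(x, rank = 1L, nRestarts = 2L, seed = 1L)
  expect_lt(fit$relError, 1e-6)
  cosine <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
  expect_gt(cosine(fit$neuronFactors[, 1], u), 0.999)
  expect_gt(cosine(fit$conditionFactors[, 1], v), 0.999)
  expect_gt(cosine(fit$timeFactors[, 1], w), 0.999)
})

test_that("the HALS objective trace is non-increasing", {
  set.seed(22)
  x <- array(runif(10 * 8 * 6), dim = c(10, 8, 6))
  fit <- ntfDecompose(x, rank = 3L, nRestarts = 1L, seed = 2L)
  expect_true(all(diff(fit$objectiveTrace) <= 1e-9))
})

test_that("well-separated rank-3 factors are recovered by greedy matching", {
  set.seed(23)
  # block-structured, nearly orthogonal planted factors
  mkFac <- function(n) {
    f <- matrix(runif(n * 3, 0, 0.05), n, 3)
    idx <- split(seq_len(n), cut(seq_len(n), 3, labels = FALSE))
    for (r in 1:3) f[idx[[r]], r] <- runif(length(idx[[r]]), 0.8, 1.2)
    f
  }
  U <- mkFac(15); V <- mkFac(12); W <- mkFac(9)
  x <- array(0, dim = c(15, 12, 9))
  for (r in 1:3) x <- x + outer(outer(U[, r], V[, r]), W[, r])
  fit <- ntfDecompose(x, rank = 3L, nRestarts = 5L, seed = 3L)
  cosine <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
  # greedy matching oracle between recovered and planted components
  C <- outer(1:3, 1:3, Vectorize(function(i, j)
    cosine(fit$neuronFactors[, i], U[, j])))
  matched <- numeric(3); usedJ <- integer(0)
  for (s in 1:3) {
    C[, usedJ] <- -Inf
    best <- which(C == max(C), arr.ind = TRUE)[1, ]
    matched[s] <- C[best[1], best[2]]
    usedJ <- c(usedJ, best[2]); C[best[1], ] <- -Inf
  }
  expect_gt(mean(matched), 0.95)
  expect_lt(fit$relError, 1e-3)
})

test_that("relative error decreases with rank on structured input", {
  set.seed(24)
  U <- matrix(runif(10 * 3), 10, 3); V <- matrix(runif(8 * 3), 8, 3)
  W <- matrix(runif(6 * 3), 6, 3)
  x <- array(0, dim = c(10, 8, 6))
  for (r in 1:3) x <- x + outer(outer(U[, r], V[, r]), W[, r])
  errs <- vapply(1:3, function(r)
    ntfDecompose(x, r, nRestarts = 3L, seed = 4L)$relError, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("excess rank warns instead of failing", {
  x <- array(runif(2 * 2 * 2), dim = c(2, 2, 2))
  expect_warning(ntfDecompose(x, rank = 5L, nRestarts = 1L, seed = 1L),
                 "feasible rank bound")
  xx <- x; xx[1, 1, 1] <- NA
  expect_error(ntfDecompose(xx, rank = 1L), "validation error")
})

test_that("the adaptive kernel graph matches its defining formula", {
  set.seed(25)
  # two groups separated by 10x the within-group scale
  g1 <- matrix(runif(10 * 4, 0, 0.1), 10, 4)
  g2 <- g1 + 2                              # far away after row-normalization
  F <- rbind(g1, g2)
  A <- neuronSimilarityGraph(F, k = 3L)
  expect_equal(A, t(A))
  expect_true(all(diag(A) == 1))
  expect_true(all(A >= 0))
  # oracle: evaluate the kernel formula directly
  Fn <- F / sqrt(rowSums(F^2))
  d <- as.matrix(dist(Fn))
  sigma <- apply(d, 1, function(r) sort(r)[4])
  expected <- exp(-d^2 / outer(sigma, sigma))
  diag(expected) <- 1
  expect_equal(unname(A), unname((expected + t(expected)) / 2),
               tolerance = 1e-12)
  expect_lt(max(A[1:10, 11:20]), 1e-4)
})

test_that("identical factor rows get unit affinity and a duplicates report", {
  F <- matrix(runif(6 * 3), 6, 3)
  F[2, ] <- F[1, ]
  A <- neuronSimilarityGraph(F, k = 1L)
  expect_equal(A[1, 2], 1)
  expect_true(all(c(1, 2) %in% attr(A, "duplicates")))
})

test_that("a two-block affinity is sign-separated by the first coordinate", {
  W <- matrix(0, 8, 8)
  W[1:4, 1:4] <- 1; W[5:8, 5:8] <- 1       # two disconnected cliques
  em <- diffusionEmbedding(W, nDims = 1L)
  x <- embedding(em)[, 1]
  expect_equal(em@eigenvalues[1], 1)
  expect_true(all(x[1:4] > 0) && all(x[5:8] < 0) ||
                all(x[1:4] < 0) && all(x[5:8] > 0))
  expect_equal(em@component, rep(c(1L, 2L), each = 4L))
  # closed form: the unit-eigenvalue coordinate is the signed block
  # indicator (orthogonalized against the constant), so it is flat
  # within blocks
  expect_lt(diff(range(x[1:4])), 1e-10)
  expect_lt(diff(range(x[5:8])), 1e-10)
})

test_that("embedding is invariant to positive scaling of the affinity", {
  set.seed(26)
  F <- matrix(runif(12 * 3), 12, 3)
  A <- neuronSimilarityGraph(F, k = 3L)
  e1 <- diffusionEmbedding(A, nDims = 3L)
  e2 <- diffusionEmbedding(7.3 * A, nDims = 3L)
  expect_equal(embedding(e1), embedding(e2), tolerance = 1e-9)
  expect_true(all(diff(e1@eigenvalues) <= 1e-9))
  expect_true(all(e1@eigenvalues > 0 & e1@eigenvalues <= 1))
})

test_that("graph and embedding are neuron-permutation equivariant", {
  set.seed(27)
  F <- matrix(runif(15 * 4), 15, 4)
  perm <- sample(15)
  e1 <- diffusionEmbedding(neuronSimilarityGraph(F, k = 4L), nDims = 3L)
  e2 <- diffusionEmbedding(neuronSimilarityGraph(F[perm, ], k = 4L),
                           nDims = 3L)
  expect_equal(embedding(e2), embedding(e1)[perm, ], tolerance = 1e-8)
})

test_that("topology statistics separate clustered from continuous layouts", {
  set.seed(28)
  blob <- matrix(rnorm(60 * 3), 60, 3)
  tsBlob <- topologyStats(blob, knn = 10L, seed = 1L)
  expect_equal(tsBlob$nComponents, 1L)
  two <- rbind(matrix(rnorm(30 * 3, 0, 0.2), 30, 3),
               matrix(rnorm(30 * 3, 8, 0.2), 30, 3))
  tsTwo <- topologyStats(two, knn = 5L, seed = 1L)
  expect_gt(tsTwo$gapRatio, 5)
  expect_equal(tsTwo$kChosen, 2L)
  expect_error(topologyStats(blob[1:2, ]), "too-few-points")
})

test_that("a typed noiseless population is recovered with ARI 1", {
  ens <- makeStimulusEnsemble(list(classes = list(A = "v1", B = "v1",
                                                  C = "v1"),
                                   nDirections = 8L))
  sim <- simulatePopulation(ens, list(
    nPerClass = 20L, nNonselective = 0L, offClassGain = 0, noiseScale = 0,
    sharedTuning = TRUE,
    profilesByClass = list(A = "transient", B = "sustained",
                           C = "periodic")), seed = 31L)
  em <- suppressWarnings(buildEncodingManifold(sim$tensor, rank = 3L,
                                               nDims = 3L, seed = 5L))
  gt <- sim$groundTruth
  lab <- gt$planted_class[match(neuronIds(em), gt$neuron_id)]
  ts <- topologyStats(em, labels = lab, seed = 2L)
  expect_equal(ts$labelARI, 1)
  expect_equal(ts$nComponents, 3L)
})
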