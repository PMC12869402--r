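test_that("zero-dispersion separated bundles score S_tight = 1", {
  b <- makeTrajectoryBundles(list(sigma = 0, separation = 5), seed = 1L)
  tg <- tightnessScore(b$trajectories)
  expect_equal(tg$sTight, 1)
  expect_equal(unname(tg$perClass), rep(1, 2))
})

test_that("coincident bundles score S_tight = 0", {
  tr <- array(rep(0, 8 * 5 * 2), dim = c(8, 5, 2))
  ts <- new("TrajectorySet", trajectories = tr,
            labels = data.frame(base_class = rep(c("a", "b"), each = 4)),
            timeAxis = 1:5, projection = list())
  expect_equal(tightnessScore(ts)$sTight, 0)
})

test_that("structured bundles outscore their label-permuted versions", {
  b <- makeTrajectoryBundles(list(sigma = 0.1, separation = 10,
                                  nPerBundle = 6L), seed = 2L)
  sObs <- tightnessScore(b$trajectories)$sTight
  tr <- trajectories(b$trajectories)
  lab <- trajectoryLabels(b$trajectories)$base_class
  wins <- 0L
  set.seed(99)
  for (i in 1:100) {
    permLab <- sample(lab)
    ts <- new("TrajectorySet", trajectories = tr,
              labels = data.frame(base_class = permLab),
              timeAxis = timeAxis(b$trajectories), projection = list())
    if (sObs > tightnessScore(ts)$sTight) wins <- wins + 1L
  }
  expect_gte(wins, 99L)
})

test_that("S_tight is monotone non-increasing in bundle dispersion", {
  sigmas <- c(0.1, 0.2, 0.4, 0.8, 1.6)
  scores <- vapply(sigmas, function(s) {
    b <- makeTrajectoryBundles(list(sigma = s, separation = 5,
                                    nPerBundle = 8L), seed = 3L)
    tightnessScore(b$trajectories)$sTight
  }, numeric(1))
  expect_true(all(diff(scores) <= 0))
})

test_that("per-class tightness averages (weighted) to the pooled score", {
  b <- makeTrajectoryBundles(list(nBundles = 3L, nPerBundle = 5L,
                                  sigma = 0.4), seed = 4L)
  tg <- tightnessScore(b$trajectories)
  n <- tg$nPerClass[names(tg$perClass)]
  expect_equal(sum(tg$perClass * n) / sum(n), tg$sTight, tolerance = 1e-9)
})

test_that("parallel disjoint bundles have no crossings", {
  b <- makeTrajectoryBundles(list(arrangement = "parallel", sigma = 0.05,
                                  separation = 10), seed = 5L)
  cr <- crossingsScore(b$trajectories)
  expect_equal(cr$sCross, 0)
  expect_true(all(cr$perTime == 0))
})

test_that("the X configuration scores one crossing per pair per run", {
  b <- makeTrajectoryBundles(list(arrangement = "cross", sigma = 0.01,
                                  T = 20L), seed = 6L)
  cr <- crossingsScore(b$trajectories)
  expect_equal(cr$sCross, 1 / 19)
  # brute-force parametric segment-intersection oracle agrees
  expect_equal(sum(cr$perTime) * cr$nPairs,
               oracleCrossBundleCrossings(b$trajectories))
})

test_that("crossings are exactly symmetric under time reversal", {
  b <- makeTrajectoryBundles(list(arrangement = "cross", sigma = 0.3,
                                  nPerBundle = 6L), seed = 7L)
  cr1 <- crossingsScore(b$trajectories)
  tr <- trajectories(b$trajectories)
  rev <- tr[, rev(seq_len(dim(tr)[2])), , drop = FALSE]
  tsRev <- new("TrajectorySet", trajectories = rev,
               labels = trajectoryLabels(b$trajectories),
               timeAxis = timeAxis(b$trajectories), projection = list())
  cr2 <- crossingsScore(tsRev)
  expect_equal(cr2$sCross, cr1$sCross)
})

test_that("both scores are invariant to rotation, shift, and scaling", {
  b <- makeTrajectoryBundles(list(nBundles = 3L, sigma = 0.3, D = 3L),
                             seed = 8L)
  base <- b$trajectories
  R <- randomRotation(3L, seed = 42L)
  moved <- transformTrajectories(base, R = R, shift = c(5, -3, 2),
                                 scale = 4.2)
  expect_equal(tightnessScore(moved)$sTight, tightnessScore(base)$sTight,
               tolerance = 1e-9)
  expect_equal(crossingsScore(moved)$sCross, crossingsScore(base)$sCross)
})

test_that("counted crossings track the planted crossing counts", {
  # sweep arrangements mixing crossing and parallel bundle pairs
  planted <- counted <- numeric(0)
  for (i in seq_len(12)) {
    arr <- if (i %% 2 == 0) "cross" else "parallel"
    b <- makeTrajectoryBundles(list(arrangement = arr, sigma = 0.02,
                                    nPerBundle = 1L + (i %% 4),
                                    T = 12L), seed = 100L + i)
    cr <- crossingsScore(b$trajectories)
    planted <- c(planted, b$plantedCrossings)
    counted <- c(counted, sum(cr$perTime) * cr$nPairs)
  }
  expect_gt(cor(planted, counted, method = "spearman"), 0.9)
})

test_that("single-class sets are rejected by both metrics", {
  b <- makeTrajectoryBundles(list(nBundles = 1L), seed = 9L)
  expect_error(tightnessScore(b$trajectories), "insufficient-classes")
  expect_error(crossingsScore(b$trajectories), "insufficient-classes")
})

test_that("comparing a set against itself gives delta 0 and p 1", {
  b <- makeTrajectoryBundles(list(sigma = 0.2), seed = 10L)
  cmp <- compareScores(b$trajectories, b$trajectories, metric = "tight",
                       nBoot = 200L, seed = 1L)
  expect_equal(cmp$delta, 0)
  expect_equal(cmp$p, 1)
  expect_warning(compareScores(b$trajectories, b$trajectories,
                               metric = "tight", nBoot = 50L, seed = 1L),
                 "nBoot")
})

test_that("planted crossings versus none are detected with Bonferroni room", {
  a <- makeTrajectoryBundles(list(arrangement = "cross", sigma = 0.05),
                             seed = 11L)
  b <- makeTrajectoryBundles(list(arrangement = "parallel", sigma = 0.05,
                                  separation = 10), seed = 12L)
  cmp <- compareScores(a$trajectories, b$trajectories, metric = "cross",
                       nBoot = 1000L, seed = 2L, nComparisons = 8L)
  expect_gt(cmp$delta, 0)
  expect_lt(cmp$pBonferroni, 0.01)
})

test_that("tubularityScores builds a valid combined object", {
  b <- makeTrajectoryBundles(list(sigma = 0.2, nBundles = 3L), seed = 13L)
  tub <- tubularityScores(b$trajectories)
  expect_s4_class(tub, "TubularityScores")
  expect_true(sTight(tub) >= 0 && sTight(tub) <= 1)
  expect_true(sCross(tub) >= 0 && sCross(tub) <= 1)
  expect_equal(tub@dims, 3L)
})
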