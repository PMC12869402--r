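# Tubularity metrics: tightness (S_tight) and crossings (S_cross) of
# labeled trajectory bundles, plus a bootstrap comparison test.

# Internal cores operate on (K x T x D array, class labels) so bootstrap
# resampling avoids S4 construction overhead.

tightnessCore <- function(tr, cls) {
  K <- dim(tr)[1]; T <- dim(tr)[2]; D <- dim(tr)[3]
  classes <- sort(unique(cls))
  C <- length(classes)
  if (C < 2)
    stop("insufficient-classes error: tightness needs at least 2 classes",
         call. = FALSE)
  ci <- match(cls, classes)
  n_c <- tabulate(ci, C)
  M <- matrix(tr, K, T * D)                   # row = trajectory, col = (t,d)
  centM <- rowsum(M, ci) / n_c                # C x (T*D) class centroids
  # within: distance of each trajectory point to its class centroid
  dif2 <- (M - centM[ci, , drop = FALSE])^2
  dists <- matrix(0, K, T)
  for (d in seq_len(D))
    dists <- dists + dif2[, (d - 1L) * T + seq_len(T), drop = FALSE]
  wc <- rowsum(sqrt(dists), ci) / n_c         # C x T
  # between: mean pairwise centroid distance per time step
  pairs <- utils::combn(C, 2)
  pd2 <- (centM[pairs[1, ], , drop = FALSE] -
            centM[pairs[2, ], , drop = FALSE])^2
  bd <- matrix(0, ncol(pairs), T)
  for (d in seq_len(D))
    bd <- bd + pd2[, (d - 1L) * T + seq_len(T), drop = FALSE]
  b <- colMeans(matrix(sqrt(bd), ncol(pairs), T))
  ratio <- function(bt, wt) ifelse(bt + 2 * wt > 0, bt / (bt + 2 * wt), 0)
  perClass <- vapply(seq_len(C), function(i) mean(ratio(b, wc[i, ])),
                     numeric(1))
  names(perClass) <- classes
  pooledW <- colSums(wc * n_c) / sum(n_c)
  list(
    sTight = sum(perClass * n_c) / sum(n_c),
    perClass = perClass,
    perTime = ratio(b, pooledW),
    nPerClass = stats::setNames(n_c, classes)
  )
}

crossingsCore <- function(tr, cls) {
  K <- dim(tr)[1]; T <- dim(tr)[2]; D <- dim(tr)[3]
  classes <- sort(unique(cls))
  C <- length(classes)
  if (C < 2)
    stop("insufficient-classes error: crossings need at least 2 classes",
         call. = FALSE)
  stopIfNot(T >= 2, "crossings need at least 2 time steps")
  cent <- array(0, dim = c(C, T, D))
  for (ci in seq_len(C)) {
    rows <- which(cls == classes[ci])
    cent[ci, , ] <- if (length(rows) == 1L) tr[rows, , ]
                    else apply(tr[rows, , , drop = FALSE], c(2, 3), mean)
  }
  events <- numeric(T - 1L)
  nPairs <- 0L
  for (ci in seq_len(C - 1L)) {
    for (cj in (ci + 1L):C) {
      # inter-centroid axis per t, oriented continuously in time
      u <- matrix(cent[ci, , ] - cent[cj, , ], nrow = T)
      nu <- sqrt(rowSums(u^2))
      for (t in seq_len(T)) {
        if (nu[t] > 0) u[t, ] <- u[t, ] / nu[t]
        else u[t, ] <- if (t > 1) u[t - 1L, ] else rep(0, D)
        if (t > 1 && sum(u[t, ] * u[t - 1L, ]) < 0) u[t, ] <- -u[t, ]
      }
      ri <- which(cls == classes[ci]); rj <- which(cls == classes[cj])
      nPairs <- nPairs + length(ri) * length(rj)
      # projections: trajectories x T
      pi_ <- matrix(0, length(ri), T); pj_ <- matrix(0, length(rj), T)
      for (t in seq_len(T)) {
        pi_[, t] <- matrix(tr[ri, t, ], nrow = length(ri)) %*% u[t, ]
        pj_[, t] <- matrix(tr[rj, t, ], nrow = length(rj)) %*% u[t, ]
      }
      for (a in seq_along(ri)) {
        dp <- sweep(pj_, 2L, pi_[a, ], "-") * -1   # pi - pj, rows j
        s <- sign(dp)
        flips <- (s[, -1L, drop = FALSE] * s[, -T, drop = FALSE]) < 0
        events <- events + colSums(flips)
      }
    }
  }
  list(sCross = sum(events) / (nPairs * (T - 1L)),
       perTime = events / nPairs, nPairs = nPairs)
}

#' Trajectory-bundle tightness score (S_tight)
#'
#' Per class c and time t, \code{w_c(t)} is the mean distance of class-c
#' trajectory points to their class centroid and \code{b(t)} the mean
#' pairwise distance between class centroids; the class score is the
#' time average of \code{b/(b + 2 w_c)} and the pooled score the
#' trajectory-count-weighted mean of class scores. Tubes with zero
#' dispersion against separated centroids score 1; coincident centroids
#' score 0. The score depends only on distance ratios, so it is invariant
#' to rotation, translation and uniform scaling.
#'
#' @param trajs a \linkS4class{TrajectorySet} with >= 2 classes and >= 2
#'   trajectories per class.
#' @return list with \code{sTight}, \code{perClass}, \code{perTime},
#'   \code{nPerClass}.
#' @export
tightnessScore <- function(trajs) {
  stopifnot(is(trajs, "TrajectorySet"))
  tightnessCore(trajectories(trajs), trajectoryLabels(trajs)$base_class)
}

#' Trajectory-bundle crossings score (S_cross)
#'
#' For every cross-class trajectory pair, both trajectories are projected
#' onto the axis joining the two class centroids at each time step (the
#' axis orientation is kept continuous in time so the undirected axis is
#' well defined even when the centroids pass through each other); a
#' crossing event is a sign flip of the projected order between
#' consecutive steps. The score is events per cross-class pair per step,
#' so it lies in [0, 1]; the per-step profile localizes crossings in
#' time. Counting sign changes makes the score exactly symmetric under
#' time reversal.
#'
#' @inheritParams tightnessScore
#' @return list with \code{sCross}, \code{perTime} (events per pair at
#'   each consecutive step), \code{nPairs}.
#' @export
crossingsScore <- function(trajs) {
  stopifnot(is(trajs, "TrajectorySet"))
  crossingsCore(trajectories(trajs), trajectoryLabels(trajs)$base_class)
}

#' Combined tubularity scores
#'
#' @inheritParams tightnessScore
#' @return a \linkS4class{TubularityScores}.
#' @export
tubularityScores <- function(trajs) {
  tg <- tightnessScore(trajs)
  cr <- crossingsScore(trajs)
  new("TubularityScores",
      sTight = tg$sTight, sCross = cr$sCross,
      perClassTightness = tg$perClass,
      perTimeTightness = tg$perTime,
      perTimeCrossings = cr$perTime,
      nTrajectories = tg$nPerClass,
      dims = dim(trajectories(trajs))[3])
}

#' Compare a tubularity metric between two systems by bootstrap
#'
#' \code{delta} is metric(A) - metric(B). The two-sided p-value is a
#' studentized bootstrap test: trajectories are resampled with
#' replacement within class in each set, the bootstrap standard error
#' of delta is estimated from the replicates, and delta/SE is referred
#' to the standard normal (floored at 1/(nBoot+1) so p stays in (0, 1]).
#' When the observed delta is exactly zero there is no evidence
#' of a difference and p = 1. The Bonferroni-corrected p multiplies by
#' \code{nComparisons} (e.g. the number of layers tested), capped at 1.
#'
#' @param trajsA,trajsB \linkS4class{TrajectorySet}s.
#' @param metric \code{"tight"} or \code{"cross"}.
#' @param nBoot bootstrap replicates (a warning is raised below 100).
#' @param seed integer.
#' @param nComparisons Bonferroni multiplicity.
#' @return list with \code{delta}, \code{p}, \code{pBonferroni},
#'   \code{boot} (the replicate deltas).
#' @export
compareScores <- function(trajsA, trajsB, metric = c("tight", "cross"),
                          nBoot = 1000L, seed = 1L, nComparisons = 1L) {
  metric <- match.arg(metric)
  if (nBoot < 100L) warning("nBoot < 100 gives an unstable p-value")
  core <- if (metric == "tight") function(tr, cls) tightnessCore(tr, cls)$sTight
          else function(tr, cls) crossingsCore(tr, cls)$sCross
  trA <- trajectories(trajsA); clsA <- trajectoryLabels(trajsA)$base_class
  trB <- trajectories(trajsB); clsB <- trajectoryLabels(trajsB)$base_class
  delta <- core(trA, clsA) - core(trB, clsB)

  resampleWithin <- function(cls) {
    idx <- integer(length(cls))
    for (c in unique(cls)) {
      rows <- which(cls == c)
      idx[rows] <- rows[sample.int(length(rows), length(rows), replace = TRUE)]
    }
    idx
  }
  boot <- numeric(nBoot)
  withSeed(seed, {
    for (b in seq_len(nBoot)) {
      ia <- resampleWithin(clsA)
      ib <- resampleWithin(clsB)
      boot[b] <- core(trA[ia, , , drop = FALSE], clsA) -
                 core(trB[ib, , , drop = FALSE], clsB)
    }
  })
  if (delta == 0) {
    p <- 1
  } else {
    s <- sd(boot)
    p <- if (s > 0) max(2 * stats::pnorm(-abs(delta / s)), 1 / (nBoot + 1))
         else 1 / (nBoot + 1)
  }
  list(delta = delta, p = p, pBonferroni = min(1, p * nComparisons),
       boot = boot)
}
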