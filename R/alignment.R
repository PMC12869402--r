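# Representational-alignment battery: RSA, CCA, linear predictivity,
# and their aggregation with DSA into a four-metric report.

#' Condition-by-feature response matrix for alignment metrics
#'
#' Rows are analysis units (conditions) under the chosen grouping,
#' columns are neurons. With \code{timeResolved = TRUE} every
#' (unit, time bin) pair becomes its own condition row, so alignment can
#' be scored on time-resolved rather than time-averaged responses.
#'
#' @param tensor a \linkS4class{ResponseTensor}.
#' @param grouping \code{"class-direction"} or \code{"sequence"}.
#' @param timeResolved logical.
#' @return numeric matrix, conditions x neurons, with a
#'   \code{"labels"} attribute carrying the unit labels.
#' @export
conditionResponses <- function(tensor,
                               grouping = c("class-direction", "sequence"),
                               timeResolved = FALSE) {
  grouping <- match.arg(grouping)
  units <- groupingUnits(ensemble(tensor), grouping)
  ua <- unitActivity(tensor, units)       # P x N x T
  P <- dim(ua)[1]; N <- dim(ua)[2]; T <- dim(ua)[3]
  if (timeResolved) {
    X <- matrix(aperm(ua, c(3, 1, 2)), nrow = P * T, ncol = N)
    attr(X, "labels") <- units$labels[rep(seq_len(P), each = T), ,
                                      drop = FALSE]
  } else {
    X <- apply(ua, c(1, 2), mean)
    attr(X, "labels") <- units$labels
  }
  X
}

#' Representational similarity analysis score
#'
#' Each system's representational dissimilarity matrix (RDM) holds the
#' correlation distance (1 - Pearson across features) between every pair
#' of condition rows; the score is the Spearman correlation between the
#' two RDMs' upper triangles. Conditions with zero feature variance in
#' either system are dropped from both (reported via a warning and the
#' \code{"dropped"} attribute).
#'
#' @param X,Y conditions x features matrices, rows aligned on the same
#'   conditions (>= 4 after dropping).
#' @return Spearman correlation in [-1, 1].
#' @export
rsaScore <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopIfNot(nrow(X) == nrow(Y), "X and Y must have the same condition count")
  sdX <- apply(X, 1, sd); sdY <- apply(Y, 1, sd)
  drop <- which(sdX == 0 | sdY == 0)
  if (length(drop) > 0L) {
    warning(sprintf("dropping %d zero-variance condition(s) from both systems",
                    length(drop)))
    X <- X[-drop, , drop = FALSE]; Y <- Y[-drop, , drop = FALSE]
  }
  stopIfNot(nrow(X) >= 4, "RSA needs at least 4 usable conditions")
  rdmX <- 1 - cor(t(X)); rdmY <- 1 - cor(t(Y))
  ut <- upper.tri(rdmX)
  out <- cor(rdmX[ut], rdmY[ut], method = "spearman")
  attr(out, "dropped") <- drop
  out
}

#' Canonical correlation alignment score
#'
#' Both systems are reduced to \code{pcaDim} principal components (the
#' regularization against rank deficiency), then the score is the mean
#' of the top \code{nComponents} canonical correlations, in [0, 1]. The
#' score is invariant to invertible linear maps of either feature space
#' that preserve the retained subspace, so \code{Y = X M} scores 1.
#'
#' @param X,Y conditions x features matrices, row-aligned.
#' @param nComponents number of canonical pairs averaged.
#' @param pcaDim PCA dimension per side (conditions >= pcaDim >=
#'   nComponents).
#' @return mean canonical correlation in [0, 1].
#' @export
ccaScore <- function(X, Y, nComponents = 5L, pcaDim = 10L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopIfNot(nrow(X) == nrow(Y), "X and Y must have the same condition count")
  n <- nrow(X)
  if (!(n > pcaDim && pcaDim >= nComponents && nComponents >= 1))
    stop(sprintf(
      "dimension error: need conditions (%d) > pcaDim (%d) >= nComponents (%d) >= 1",
      n, pcaDim, nComponents), call. = FALSE)
  red <- function(M) {
    r <- min(pcaDim, ncol(M), n - 1L)
    prcomp(M, center = TRUE, scale. = FALSE, rank. = r)$x[, seq_len(r),
                                                          drop = FALSE]
  }
  Sx <- red(X); Sy <- red(Y)
  if (nComponents > min(ncol(Sx), ncol(Sy)))
    stop(sprintf(
      "dimension error: nComponents (%d) exceeds the feasible rank (%d)",
      nComponents, min(ncol(Sx), ncol(Sy))), call. = FALSE)
  # guard exact rank deficiency inside cancor with a hair of jitter-free
  # truncation: drop numerically-zero-variance PCs
  keep <- function(S) S[, apply(S, 2, sd) > 1e-12, drop = FALSE]
  Sx <- keep(Sx); Sy <- keep(Sy)
  stopIfNot(min(ncol(Sx), ncol(Sy)) >= nComponents,
            "dimension error: too few informative components")
  cc <- cancor(Sx, Sy)
  rho <- cc$cor[seq_len(nComponents)]
  mean(pmin(pmax(rho, 0), 1))
}

#' Cross-validated linear predictivity
#'
#' Ridge-regresses the target system on the source system with k-fold
#' cross-validation; the score is the mean over target features of the
#' Pearson correlation between pooled out-of-fold predictions and the
#' true values. Directional: see \code{\link{alignmentReport}}, which
#' stores both directions. Zero-variance target features are excluded
#' (reported via warning).
#'
#' @param X source conditions x features matrix.
#' @param Y target conditions x features matrix.
#' @param folds number of folds (conditions >= folds >= 2).
#' @param ridge nonnegative ridge penalty.
#' @param seed fold-assignment seed.
#' @return mean out-of-fold correlation in [-1, 1].
#' @export
linearPredictivity <- function(X, Y, folds = 5L, ridge = 1e-3, seed = 1L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  stopIfNot(n == nrow(Y), "X and Y must have the same condition count")
  stopIfNot(n >= folds && folds >= 2, "need conditions >= folds >= 2")
  stopIfNot(ridge >= 0, "ridge must be nonnegative")
  keep <- which(apply(Y, 2, sd) > 0)
  if (length(keep) < ncol(Y))
    warning(sprintf("excluding %d zero-variance target feature(s)",
                    ncol(Y) - length(keep)))
  stopIfNot(length(keep) >= 1, "no target features with variance left")
  Y <- Y[, keep, drop = FALSE]
  fold <- integer(n)
  withSeed(seed, fold <- rep_len(seq_len(folds), n)[sample.int(n)])
  pred <- matrix(NA_real_, n, ncol(Y))
  for (f in seq_len(folds)) {
    test <- which(fold == f)
    fit <- ridgeFit(X[-test, , drop = FALSE], Y[-test, , drop = FALSE],
                    max(ridge, 1e-12))
    pred[test, ] <- fit(X[test, , drop = FALSE])
  }
  rs <- vapply(seq_len(ncol(Y)), function(j) {
    if (sd(pred[, j]) == 0) 0 else cor(pred[, j], Y[, j])
  }, numeric(1))
  mean(rs)
}

#' Four-metric representational alignment report
#'
#' Computes RSA, CCA, linear predictivity (both directions, averaged)
#' on the condition-by-feature matrices and DSA on the trajectory sets,
#' plus the plain arithmetic mean of the four scores.
#'
#' @param X,Y conditions x features matrices, row-aligned.
#' @param trajsX,trajsY \linkS4class{TrajectorySet}s for the two systems.
#' @param config list overriding defaults: \code{ccaComponents},
#'   \code{ccaPcaDim}, \code{lpFolds}, \code{lpRidge}, \code{dsaRank},
#'   \code{dsaRestarts}, \code{seed}.
#' @return an \linkS4class{AlignmentReport}.
#' @export
alignmentReport <- function(X, Y, trajsX, trajsY, config = list()) {
  cfg <- modifyList(list(ccaComponents = 5L, ccaPcaDim = 10L,
                         lpFolds = 5L, lpRidge = 1e-3,
                         dsaRank = 5L, dsaRestarts = 10L, seed = 1L),
                    config)
  rsa <- as.numeric(rsaScore(X, Y))
  cca <- ccaScore(X, Y, nComponents = cfg$ccaComponents,
                  pcaDim = cfg$ccaPcaDim)
  lpXY <- linearPredictivity(X, Y, folds = cfg$lpFolds, ridge = cfg$lpRidge,
                             seed = cfg$seed)
  lpYX <- linearPredictivity(Y, X, folds = cfg$lpFolds, ridge = cfg$lpRidge,
                             seed = cfg$seed)
  lp <- mean(c(lpXY, lpYX))
  dsa <- dsaScore(trajsX, trajsY, rank = cfg$dsaRank,
                  nRestarts = cfg$dsaRestarts, seed = cfg$seed)
  new("AlignmentReport", rsa = rsa, cca = cca, lp = lp,
      lpXY = lpXY, lpYX = lpYX, dsa = dsa,
      meanScore = mean(c(rsa, cca, lp, dsa)), config = cfg)
}

#' Serialize an AlignmentReport to JSON
#'
#' @param report an \linkS4class{AlignmentReport}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeAlignmentReport <- function(report, path) {
  jsonlite::write_json(
    list(rsa = report@rsa, cca = report@cca, lp = report@lp,
         lp_xy = report@lpXY, lp_yx = report@lpYX, dsa = report@dsa,
         mean_score = report@meanScore, config = report@config),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
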