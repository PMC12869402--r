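# Decoding-side analyses: PCA manifolds of time-averaged activity,
# time-resolved decoding trajectories, classification accuracy, and
# neuron ablation.

# Analysis units under a grouping: a list with
#   labels: data.frame (base_class, direction [, sequence_id])
#   index:  list of sequence-row indices contributing to each unit
groupingUnits <- function(ensemble, grouping = c("class-direction", "sequence")) {
  grouping <- match.arg(grouping)
  sq <- sequenceTable(ensemble)
  if (grouping == "sequence") {
    list(
      labels = data.frame(sequence_id = sq$sequence_id,
                          base_class = sq$base_class,
                          direction = sq$direction,
                          stringsAsFactors = FALSE),
      index = as.list(seq_len(nrow(sq)))
    )
  } else {
    key <- paste(sq$base_class, sq$direction, sep = "\r")
    uk <- unique(key)
    idx <- lapply(uk, function(k) which(key == k))
    first <- match(uk, key)
    list(
      labels = data.frame(base_class = sq$base_class[first],
                          direction = sq$direction[first],
                          stringsAsFactors = FALSE),
      index = idx
    )
  }
}

# Unit x neuron matrix of variant-averaged activity; time kept as the
# third axis (units x neurons x time).
unitActivity <- function(tensor, units) {
  a <- activity(tensor)
  N <- dim(a)[1]; T <- dim(a)[3]
  P <- length(units$index)
  out <- array(0, dim = c(P, N, T))
  for (p in seq_len(P)) {
    rows <- units$index[[p]]
    if (length(rows) == 1L) out[p, , ] <- a[, rows, ]
    else out[p, , ] <- apply(a[, rows, , drop = FALSE], c(1, 3), mean)
  }
  out
}

#' Build a decoding manifold by PCA of time-averaged activity
#'
#' Each analysis unit (a unique sequence, or a class-direction cell after
#' averaging spatial-frequency variants) becomes one point: its
#' time-averaged population activity vector, mean-centered across units
#' and projected onto the top principal axes. Under the default ensemble
#' and class-direction grouping the manifold has 48 points.
#'
#' @param tensor a \linkS4class{ResponseTensor}.
#' @param nDims number of principal components to keep.
#' @param grouping \code{"class-direction"} (default) or \code{"sequence"}.
#' @return a \linkS4class{DecodingManifold}.
#' @export
buildDecodingManifold <- function(tensor, nDims = 3L,
                                  grouping = c("class-direction", "sequence")) {
  grouping <- match.arg(grouping)
  units <- groupingUnits(ensemble(tensor), grouping)
  ua <- unitActivity(tensor, units)
  X <- apply(ua, c(1, 2), mean)          # units x neurons, time-averaged
  P <- nrow(X); N <- ncol(X)
  if (nDims > min(P, N))
    stop(sprintf(
      "dimension error: nDims = %d exceeds min(units, neurons) = %d",
      nDims, min(P, N)), call. = FALSE)
  pc <- prcomp(X, center = TRUE, scale. = FALSE, rank. = nDims)
  tot <- sum(apply(X, 2, var))
  evr <- if (tot > 0) pc$sdev[seq_len(nDims)]^2 / tot else rep(0, nDims)
  new("DecodingManifold",
      coords = unname(pc$x[, seq_len(nDims), drop = FALSE]),
      pointLabels = units$labels,
      explainedVarianceRatio = evr,
      projection = list(center = pc$center,
                        rotation = unname(pc$rotation[, seq_len(nDims),
                                                      drop = FALSE]),
                        grouping = grouping))
}

#' Build decoding trajectories by PCA of pooled time points
#'
#' Every (analysis unit, time step) pair is one point in neuron space;
#' PCA is fit on this pooled cloud, and each unit's T projected points
#' form one labeled trajectory. Because the projection is linear, the
#' time-average of a trajectory equals the projection of the unit's
#' time-averaged activity through the same map.
#'
#' @inheritParams buildDecodingManifold
#' @return a \linkS4class{TrajectorySet} with the fitted projection
#'   (center, rotation, explained variance) in \code{projection(x)}.
#' @export
buildDecodingTrajectories <- function(tensor, nDims = 3L,
                                      grouping = c("class-direction", "sequence")) {
  grouping <- match.arg(grouping)
  units <- groupingUnits(ensemble(tensor), grouping)
  ua <- unitActivity(tensor, units)      # P x N x T
  P <- dim(ua)[1]; N <- dim(ua)[2]; T <- dim(ua)[3]
  stopIfNot(T >= 2, "decoding trajectories need at least 2 time bins")
  # rows ordered unit-major with time fastest: row = (p-1)*T + t
  pooled <- matrix(aperm(ua, c(3, 1, 2)), nrow = P * T, ncol = N)
  if (nDims > min(nrow(pooled), N))
    stop(sprintf(
      "dimension error: nDims = %d exceeds min(points, neurons) = %d",
      nDims, min(nrow(pooled), N)), call. = FALSE)
  pc <- prcomp(pooled, center = TRUE, scale. = FALSE, rank. = nDims)
  proj <- unname(pc$x[, seq_len(nDims), drop = FALSE])
  tr <- array(0, dim = c(P, T, nDims))
  for (p in seq_len(P)) tr[p, , ] <- proj[(p - 1L) * T + seq_len(T), ]
  tot <- sum(apply(pooled, 2, var))
  evr <- if (tot > 0) pc$sdev[seq_len(nDims)]^2 / tot else rep(0, nDims)
  new("TrajectorySet", trajectories = tr, labels = units$labels,
      timeAxis = timeAxis(tensor),
      projection = list(center = pc$center,
                        rotation = unname(pc$rotation[, seq_len(nDims),
                                                      drop = FALSE]),
                        explainedVarianceRatio = evr,
                        grouping = grouping))
}

#' Classification accuracy of base class from population activity
#'
#' Predicts each analysis unit's base-stimulus class from its
#' time-averaged population activity vector. \code{nearest-centroid-loo}
#' is leave-one-unit-out nearest class centroid (Euclidean; ties broken
#' toward the lowest class index); \code{linear-cv} is stratified k-fold
#' ridge regression onto class indicators with argmax decoding.
#'
#' @param tensor a \linkS4class{ResponseTensor}.
#' @param scheme classifier scheme.
#' @param grouping analysis-unit grouping, as in
#'   \code{\link{buildDecodingManifold}}.
#' @param folds number of folds for \code{linear-cv}.
#' @param ridge ridge penalty for \code{linear-cv}.
#' @param seed fold-assignment seed for \code{linear-cv}.
#' @param labels optional replacement class labels (one per unit), e.g.
#'   for shuffle controls.
#' @return fraction of units classified correctly, in [0, 1].
#' @export
classificationAccuracy <- function(tensor,
                                   scheme = c("nearest-centroid-loo", "linear-cv"),
                                   grouping = c("class-direction", "sequence"),
                                   folds = 5L, ridge = 1e-3, seed = 1L,
                                   labels = NULL) {
  scheme <- match.arg(scheme)
  grouping <- match.arg(grouping)
  units <- groupingUnits(ensemble(tensor), grouping)
  X <- apply(unitActivity(tensor, units), c(1, 2), mean)
  y <- if (is.null(labels)) units$labels$base_class else as.character(labels)
  stopIfNot(length(y) == nrow(X), "labels must have one entry per analysis unit")
  classes <- unique(y)
  stopIfNot(length(classes) >= 2, "need at least 2 classes")
  counts <- table(y)
  if (scheme == "nearest-centroid-loo") {
    if (any(counts < 2))
      stop(sprintf(
        "degenerate-class error: class '%s' has a single unit under leave-one-out",
        names(counts)[which(counts < 2)[1]]), call. = FALSE)
    pred <- character(nrow(X))
    for (i in seq_len(nrow(X))) {
      cent <- t(vapply(classes, function(cl) {
        rows <- setdiff(which(y == cl), i)
        colMeans(X[rows, , drop = FALSE])
      }, numeric(ncol(X))))
      d2 <- rowSums(sweep(cent, 2L, X[i, ])^2)
      pred[i] <- classes[which.min(d2)]   # which.min: lowest index on ties
    }
    mean(pred == y)
  } else {
    stopIfNot(folds >= 2 && folds <= nrow(X), "folds must be in [2, units]")
    if (any(counts < 2))
      stop(sprintf(
        "degenerate-class error: class '%s' has a single unit",
        names(counts)[which(counts < 2)[1]]), call. = FALSE)
    fold <- stratifiedFolds(y, folds, seed)
    Yind <- outer(y, classes, "==") * 1
    pred <- character(nrow(X))
    for (f in seq_len(folds)) {
      test <- which(fold == f)
      if (length(test) == 0L) next
      fit <- ridgeFit(X[-test, , drop = FALSE], Yind[-test, , drop = FALSE],
                      ridge)
      sc <- fit(X[test, , drop = FALSE])
      pred[test] <- classes[max.col(sc, ties.method = "first")]
    }
    mean(pred == y)
  }
}

#' Remove a set of neurons from a tensor
#'
#' Returns the tensor restricted to the complement of \code{neuronIds},
#' e.g. to ablate the nonselective "intensity" units before rebuilding
#' manifolds and trajectories.
#'
#' @param tensor a \linkS4class{ResponseTensor}.
#' @param ids neuron ids to remove.
#' @return a \linkS4class{ResponseTensor} without those neurons.
#' @export
ablateNeurons <- function(tensor, ids) {
  ids <- as.character(ids)
  unknown <- setdiff(ids, neuronIds(tensor))
  if (length(unknown) > 0L)
    stop(sprintf("lookup error: unknown neuron id(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  keep <- !(neuronIds(tensor) %in% ids)
  if (!any(keep))
    stop("validation error: ablating all neurons leaves an empty tensor",
         call. = FALSE)
  ResponseTensor(activity(tensor)[keep, , , drop = FALSE],
                 binWidth = binWidth(tensor), ensemble = ensemble(tensor),
                 neuronIds = neuronIds(tensor)[keep])
}
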