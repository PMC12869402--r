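# Fixture builders and independent oracles used across the suite.

# Small typed ensemble: nClasses classes, one variant each, 8 directions.
tinyEnsemble <- function(nClasses = 2L, nDirections = 8L) {
  cls <- as.list(rep("v1", nClasses))
  names(cls) <- LETTERS[seq_len(nClasses)]
  makeStimulusEnsemble(list(classes = cls, nDirections = nDirections))
}

# Hand-built tensor from an activity array (wraps construction details).
tensorFrom <- function(a, ens, binWidth = 0.05,
                       ids = sprintf("u%02d", seq_len(dim(a)[1]))) {
  ResponseTensor(a, binWidth = binWidth, ensemble = ens, neuronIds = ids)
}

# Brute-force silhouette: mean over points of (b - a)/max(a, b) with
# a = mean intra-cluster distance, b = min over other clusters of the
# mean distance to that cluster. Direct transcription of the definition.
bruteSilhouette <- function(X, labels) {
  X <- as.matrix(X)
  n <- nrow(X)
  d <- as.matrix(dist(X))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) < 2L) { s[i] <- 0; next }
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl)
      mean(d[i, labels == cl]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Brute-force count of proper intersections between two 2-D polylines,
# solving each segment pair parametrically (independent of the package's
# orientation-test implementation).
oracleSegmentCrossings <- function(P, Q) {
  count <- 0L
  for (i in seq_len(nrow(P) - 1L)) {
    for (j in seq_len(nrow(Q) - 1L)) {
      p <- P[i, ]; r <- P[i + 1L, ] - p
      q <- Q[j, ]; s <- Q[j + 1L, ] - q
      den <- r[1] * s[2] - r[2] * s[1]
      if (abs(den) < 1e-14) next            # parallel
      t <- ((q[1] - p[1]) * s[2] - (q[2] - p[2]) * s[1]) / den
      u <- ((q[1] - p[1]) * r[2] - (q[2] - p[2]) * r[1]) / den
      if (t > 1e-12 && t < 1 - 1e-12 && u > 1e-12 && u < 1 - 1e-12)
        count <- count + 1L
    }
  }
  count
}

# Total pairwise trajectory crossings between two labeled bundles of a
# TrajectorySet, counted in the first two dimensions.
oracleCrossBundleCrossings <- function(trajs) {
  tr <- trajectories(trajs)
  cls <- trajectoryLabels(trajs)$base_class
  ucl <- sort(unique(cls))
  stopifnot(length(ucl) == 2L)
  ri <- which(cls == ucl[1]); rj <- which(cls == ucl[2])
  total <- 0L
  for (a in ri) for (b in rj)
    total <- total + oracleSegmentCrossings(tr[a, , 1:2], tr[b, , 1:2])
  total
}

# Apply a rigid/similarity transform to every trajectory of a set.
transformTrajectories <- function(trajs, R = NULL, shift = NULL, scale = 1) {
  tr <- trajectories(trajs)
  D <- dim(tr)[3]
  if (is.null(R)) R <- diag(D)
  if (is.null(shift)) shift <- rep(0, D)
  out <- array(0, dim = dim(tr))
  for (k in seq_len(dim(tr)[1]))
    out[k, , ] <- sweep(scale * (tr[k, , ] %*% t(R)), 2L, shift, "+")
  new("TrajectorySet", trajectories = out, labels = trajectoryLabels(trajs),
      timeAxis = timeAxis(trajs), projection = list())
}

# Random rotation matrix (QR of a Gaussian matrix, det fixed to +1).
randomRotation <- function(D, seed) {
  set.seed(seed)
  Q <- qr.Q(qr(matrix(rnorm(D * D), D, D)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Mean path length (sum of consecutive-step distances) per trajectory.
meanPathLength <- function(trajs) {
  tr <- trajectories(trajs)
  K <- dim(tr)[1]; T <- dim(tr)[2]
  mean(vapply(seq_len(K), function(k) {
    dif <- diff(tr[k, , , drop = TRUE])
    sum(sqrt(rowSums(matrix(dif, nrow = T - 1L)^2)))
  }, numeric(1)))
}
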