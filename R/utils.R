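# Internal helpers shared across modules.

# Regular direction grid in degrees: n points starting at 0, CCW.
directionGrid <- function(n) {
  seq(0, 360 - 360 / n, by = 360 / n)
}

# Run code with a temporarily-set RNG state, restoring the caller's.
withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

# Stage seeds derived from one global seed; kept below 2^31.
deriveSeed <- function(seed, stage) {
  offsets <- c(simulate = 101L, simulate2 = 211L, bundles = 307L,
               decoding = 401L, encoding = 503L, tubularity = 601L,
               alignment = 701L, dynamics = 809L)
  if (!stage %in% names(offsets))
    stop(sprintf("unknown pipeline stage '%s'", stage), call. = FALSE)
  (as.integer(seed) %% 1000000L) * 1000L + offsets[[stage]]
}

stopIfNot <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
}

# Squared Euclidean distances between rows of two matrices.
crossdist2 <- function(A, B) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

# Ridge regression fit: solve (X'X + lambda I) B = X'Y on centered data;
# returns function(newX) -> predictions. Exact closed form.
ridgeFit <- function(X, Y, lambda) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2L, cx); Yc <- sweep(Y, 2L, cy)
  G <- crossprod(Xc) + diag(lambda, ncol(Xc))
  B <- solve(G, crossprod(Xc, Yc))
  function(newX) {
    sweep(sweep(as.matrix(newX), 2L, cx) %*% B, 2L, cy, "+")
  }
}

# Stratified k-fold assignment (seeded): per class, shuffle and deal
# units round-robin into folds.
stratifiedFolds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  withSeed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# Flatten a K x T x D trajectory array into a (K*T) x D matrix of points.
poolTrajectoryPoints <- function(tr) {
  K <- dim(tr)[1]; T <- dim(tr)[2]; D <- dim(tr)[3]
  matrix(aperm(tr, c(2, 1, 3)), nrow = K * T, ncol = D)
}
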