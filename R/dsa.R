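# Dynamical similarity analysis: compare fitted linear dynamics
# operators between two systems up to an orthogonal change of basis.

# Reduce a K x T x D trajectory array to `rank` PCA dims and fit the
# least-squares one-step predictor A over all within-trajectory
# transitions. Returns the operator and the number of transitions.
fitDynamicsOperator <- function(tr, rank) {
  K <- dim(tr)[1]; T <- dim(tr)[2]
  stopIfNot(T >= 3, "DSA needs trajectories with at least 3 time steps")
  pooled <- poolTrajectoryPoints(tr)
  r <- min(rank, ncol(pooled), nrow(pooled) - 1L)
  pc <- prcomp(pooled, center = TRUE, scale. = FALSE, rank. = r)
  Z <- pc$x[, seq_len(r), drop = FALSE]
  # rows of Z are ordered trajectory-major (t fastest within trajectory)
  X0 <- NULL; X1 <- NULL
  for (k in seq_len(K)) {
    rows <- (k - 1L) * T + seq_len(T)
    X0 <- rbind(X0, Z[rows[-T], , drop = FALSE])
    X1 <- rbind(X1, Z[rows[-1L], , drop = FALSE])
  }
  nTrans <- nrow(X0)
  if (nTrans < r) {
    warning(sprintf("only %d transitions available; reducing rank to %d",
                    nTrans, nTrans))
    r <- nTrans
    Z <- Z[, seq_len(r), drop = FALSE]
    X0 <- X0[, seq_len(r), drop = FALSE]
    X1 <- X1[, seq_len(r), drop = FALSE]
  }
  G <- crossprod(X0) + diag(1e-10, ncol(X0))
  A <- t(solve(G, crossprod(X0, X1)))
  list(A = A, rank = ncol(A), nTransitions = nTrans)
}

# Cayley map: skew-symmetric params -> special orthogonal matrix.
cayleyQ <- function(theta, r) {
  S <- matrix(0, r, r)
  S[upper.tri(S)] <- theta
  S <- S - t(S)
  solve(diag(r) - S, diag(r) + S)
}

# Minimize ||AX - Q0 C(theta) AY C(theta)' Q0'||_F over theta for a
# fixed start Q0; returns the best objective found.
procrustesDissim <- function(AX, AY, nRestarts, seed) {
  r <- nrow(AX)
  denom <- max(norm(AX, "F"), norm(AY, "F"))
  if (denom == 0) return(0)
  obj <- function(theta, Q0) {
    Q <- Q0 %*% cayleyQ(theta, r)
    norm(AX - Q %*% AY %*% t(Q), "F") / denom
  }
  nTheta <- r * (r - 1L) / 2L
  starts <- list(diag(r))
  if (r <= 6L) {
    # all diagonal sign matrices: covers PCA sign ambiguity and the
    # reflection component of O(r)
    signs <- as.matrix(expand.grid(rep(list(c(1, -1)), r)))
    for (i in seq_len(nrow(signs))) starts[[length(starts) + 1L]] <-
      diag(signs[i, ], r)
  }
  withSeed(seed, {
    for (j in seq_len(nRestarts)) {
      M <- matrix(rnorm(r * r), r, r)
      starts[[length(starts) + 1L]] <- qr.Q(qr(M))
    }
  })
  best <- Inf
  for (Q0 in starts) {
    if (nTheta == 0L) {
      val <- obj(numeric(0), Q0)
    } else {
      fit <- tryCatch(
        stats::optim(rep(0, nTheta), obj, Q0 = Q0, method = "BFGS",
                     control = list(maxit = 200, reltol = 1e-12)),
        error = function(e) list(value = obj(rep(0, nTheta), Q0)))
      val <- fit$value
    }
    if (val < best) best <- val
  }
  best
}

#' Dynamical similarity analysis score
#'
#' Each system's pooled trajectory points are reduced to \code{rank}
#' principal components and a one-step linear predictor A is fitted by
#' least squares over all within-trajectory transitions. The
#' dissimilarity is the minimum over orthogonal transforms Q of
#' \code{||A_X - Q A_Y Q'||_F / max(||A_X||_F, ||A_Y||_F)}, found by
#' multi-start optimization over the orthogonal group (Cayley-
#' parameterized rotations from identity, sign-matrix and random
#' orthogonal starts, so both components of O(r) are searched); the
#' score is \code{1 - min(1, dissimilarity)}, in [0, 1]. By
#' construction the score is invariant to orthogonal transforms of
#' either system's state space.
#'
#' @param trajsX,trajsY \linkS4class{TrajectorySet}s with T >= 3.
#' @param rank state dimension after PCA reduction (reduced with a
#'   warning if transitions are scarce).
#' @param nRestarts random orthogonal starts for the Q search.
#' @param seed integer.
#' @return similarity score in [0, 1].
#' @export
dsaScore <- function(trajsX, trajsY, rank = 5L, nRestarts = 10L, seed = 1L) {
  stopifnot(is(trajsX, "TrajectorySet"), is(trajsY, "TrajectorySet"))
  fx <- fitDynamicsOperator(trajectories(trajsX), rank)
  fy <- fitDynamicsOperator(trajectories(trajsY), rank)
  r <- min(fx$rank, fy$rank)
  AX <- fx$A[seq_len(r), seq_len(r), drop = FALSE]
  AY <- fy$A[seq_len(r), seq_len(r), drop = FALSE]
  d <- procrustesDissim(AX, AY, nRestarts = nRestarts, seed = seed)
  1 - min(1, d)
}
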