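# Nonnegative CP tensor factorization (HALS) for encoding analyses.

#' Assemble the neurons x conditions x time encoding tensor
#'
#' Conditions are the flattened (class, variant, direction) sequences in
#' ensemble order. \code{per-neuron-max} rescales each neuron's slab to
#' peak 1 so the factorization reflects response shape rather than raw
#' gain; neurons with all-zero activity are left at zero and flagged for
#' exclusion from downstream embedding.
#'
#' @param tensor a \linkS4class{ResponseTensor}.
#' @param normalization \code{"per-neuron-max"} or \code{"none"}.
#' @return list with \code{values} (N x S x T array), \code{conditions}
#'   (the sequence table), \code{neuronIds}, and \code{zeroNeurons}
#'   (character ids of flagged all-zero neurons).
#' @export
encodingTensor <- function(tensor, normalization = c("per-neuron-max", "none")) {
  normalization <- match.arg(normalization)
  a <- activity(tensor)
  ids <- neuronIds(tensor)
  peaks <- apply(a, 1, max)
  zero <- ids[peaks == 0]
  if (normalization == "per-neuron-max") {
    scale <- ifelse(peaks > 0, peaks, 1)
    a <- a / array(scale, dim = dim(a))
  }
  list(values = a, conditions = sequenceTable(ensemble(tensor)),
       neuronIds = ids, zeroNeurons = zero)
}

# Mode-n unfolding helpers (mode index first, remaining axes in order).
unfoldTensor <- function(x, mode) {
  d <- dim(x)
  perm <- c(mode, setdiff(1:3, mode))
  matrix(aperm(x, perm), nrow = d[mode])
}

# Khatri-Rao product: columnwise Kronecker, (rows(A)*rows(B)) x R with
# B's row index fastest.
khatriRao <- function(A, B) {
  R <- ncol(A)
  out <- matrix(0, nrow(A) * nrow(B), R)
  for (r in seq_len(R)) out[, r] <- kronecker(A[, r], B[, r])
  out
}

#' Nonnegative CP decomposition by hierarchical alternating least squares
#'
#' Factorizes a nonnegative 3-axis tensor into \code{rank} rank-1
#' components with nonnegative factors, minimizing Frobenius error with
#' HALS column updates (each update is a nonnegative exact coordinate
#' minimizer, so the objective is non-increasing). The best of
#' \code{nRestarts} seeded random initializations is returned.
#'
#' @param tensor3 nonnegative 3-axis array.
#' @param rank number of components (>= 1).
#' @param nRestarts number of seeded restarts.
#' @param seed base seed; restart j uses \code{seed + j - 1}.
#' @param maxIter maximum HALS sweeps per restart.
#' @param tol stop when the relative error improves by less than this
#'   between sweeps.
#' @return list with \code{neuronFactors}, \code{conditionFactors},
#'   \code{timeFactors} (nonnegative matrices with \code{rank} columns),
#'   \code{relError} (residual norm over tensor norm), and
#'   \code{objectiveTrace} (relative error after each sweep of the
#'   winning restart).
#' @export
ntfDecompose <- function(tensor3, rank, nRestarts = 3L, seed = 1L,
                         maxIter = 200L, tol = 1e-8) {
  stopIfNot(length(dim(tensor3)) == 3, "tensor3 must be a 3-axis array")
  if (any(!is.finite(tensor3)))
    stop("validation error: tensor contains non-finite values", call. = FALSE)
  stopIfNot(all(tensor3 >= 0), "tensor3 must be nonnegative")
  stopIfNot(rank >= 1, "rank must be at least 1")
  d <- dim(tensor3)
  bound <- min(d[1] * d[2], d[1] * d[3], d[2] * d[3])
  if (rank > bound)
    warning(sprintf("rank %d exceeds the feasible rank bound %d", rank, bound))

  X1 <- unfoldTensor(tensor3, 1)
  X2 <- unfoldTensor(tensor3, 2)
  X3 <- unfoldTensor(tensor3, 3)
  normX2 <- sum(tensor3^2)
  normX <- sqrt(normX2)
  if (normX == 0) {
    zf <- function(n) matrix(0, n, rank)
    return(list(neuronFactors = zf(d[1]), conditionFactors = zf(d[2]),
                timeFactors = zf(d[3]), relError = 0, objectiveTrace = 0))
  }

  halsSweepMode <- function(U, M, G) {
    # U: factor being updated; M = X_(m) %*% KR; G = Hadamard of Grams
    for (r in seq_len(ncol(U))) {
      g <- G[r, r]
      if (g <= .Machine$double.eps) next
      u <- U[, r] + (M[, r] - U %*% G[, r]) / g
      U[, r] <- pmax(u, 0)
    }
    U
  }

  best <- NULL
  for (j in seq_len(nRestarts)) {
    withSeed(seed + j - 1L, {
      U1 <- matrix(runif(d[1] * rank), d[1], rank)
      U2 <- matrix(runif(d[2] * rank), d[2], rank)
      U3 <- matrix(runif(d[3] * rank), d[3], rank)
    })
    trace <- numeric(0)
    prevErr <- Inf
    for (it in seq_len(maxIter)) {
      U1 <- halsSweepMode(U1, X1 %*% khatriRao(U3, U2),
                          crossprod(U2) * crossprod(U3))
      U2 <- halsSweepMode(U2, X2 %*% khatriRao(U3, U1),
                          crossprod(U1) * crossprod(U3))
      G12 <- crossprod(U1) * crossprod(U2)
      M3 <- X3 %*% khatriRao(U2, U1)
      U3 <- halsSweepMode(U3, M3, G12)
      fit2 <- sum((crossprod(U3) * G12))
      inner <- sum(M3 * U3)
      err <- sqrt(max(0, normX2 - 2 * inner + fit2)) / normX
      trace <- c(trace, err)
      if (prevErr - err < tol) break
      prevErr <- err
    }
    if (is.null(best) || err < best$relError) {
      best <- list(neuronFactors = U1, conditionFactors = U2,
                   timeFactors = U3, relError = err, objectiveTrace = trace)
    }
  }
  best
}

#' Pick a CP rank by the elbow rule on reconstruction error
#'
#' Returns the smallest rank whose relative-error improvement over the
#' previous rank falls below \code{threshold} (fraction of the previous
#' error), scanning 1..\code{maxRank}.
#'
#' @param tensor3 nonnegative 3-axis array.
#' @param maxRank largest rank to consider.
#' @param threshold relative improvement cutoff (default 0.05).
#' @param nRestarts,seed passed to \code{\link{ntfDecompose}}.
#' @return list with \code{rank} and \code{errors} (per scanned rank).
#' @export
selectRank <- function(tensor3, maxRank = 8L, threshold = 0.05,
                       nRestarts = 2L, seed = 1L) {
  errs <- numeric(maxRank)
  for (r in seq_len(maxRank)) {
    errs[r] <- ntfDecompose(tensor3, r, nRestarts = nRestarts,
                            seed = seed + 100L * r)$relError
    if (r > 1L) {
      prev <- errs[r - 1L]
      impr <- if (prev > 0) (prev - errs[r]) / prev else 0
      if (impr < threshold)
        return(list(rank = r - 1L, errors = errs[seq_len(r)]))
    }
    if (errs[r] < 1e-9) return(list(rank = r, errors = errs[seq_len(r)]))
  }
  list(rank = maxRank, errors = errs)
}
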