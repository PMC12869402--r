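# Adaptive-kernel similarity graph, diffusion-map embedding, and
# manifold topology summaries.

#' Adaptive Gaussian similarity graph between neurons
#'
#' Rows of \code{neuronFactors} are L2-normalized, and affinities use a
#' Gaussian kernel with local scales: \code{sigma_i} is the Euclidean
#' distance to the i-th row's k-th nearest neighbor, and
#' \code{A_ij = exp(-d_ij^2 / (sigma_i sigma_j))}. The matrix is exactly
#' symmetric with unit diagonal. Zero local scales from duplicated rows
#' are floored at a machine-scaled epsilon and the duplicates reported in
#' \code{attr(x, "duplicates")}.
#'
#' @param neuronFactors N x R nonnegative loading matrix (rank factors of
#'   the encoding tensor).
#' @param k neighbor index for the local scale (k < N).
#' @return N x N symmetric nonnegative affinity matrix.
#' @export
neuronSimilarityGraph <- function(neuronFactors, k = 7L) {
  F <- as.matrix(neuronFactors)
  N <- nrow(F)
  stopIfNot(k >= 1 && k < N, "k must satisfy 1 <= k < N")
  nrm <- sqrt(rowSums(F^2))
  nrm[nrm == 0] <- 1
  F <- F / nrm
  d2 <- crossdist2(F, F)
  d <- sqrt(d2)
  # k-th neighbor distance, self excluded
  sigma <- apply(d, 1, function(row) sort(row)[k + 1L])
  dup <- which(sigma <= 0)
  floorEps <- max(d) * 1e-12 + .Machine$double.eps
  sigma <- pmax(sigma, floorEps)
  A <- exp(-d2 / outer(sigma, sigma))
  A <- (A + t(A)) / 2
  diag(A) <- 1
  if (length(dup) > 0L) attr(A, "duplicates") <- dup
  A
}

#' Diffusion-map embedding of an affinity graph
#'
#' Row-normalizes the affinity to a Markov transition matrix and embeds
#' each node with the top nontrivial right eigenvectors scaled by
#' \code{lambda^diffusionTime}. The trivial constant eigenvector is
#' removed by deflation, so for a disconnected graph the remaining
#' unit-eigenvalue directions are the (deterministic) signed component
#' indicators and the leading coordinates separate components exactly;
#' component labels are also reported. Each eigenvector's
#' largest-magnitude entry is made positive, so the embedding is
#' deterministic up to this fixed sign convention, and row normalization
#' makes it invariant to any positive rescaling of the affinity.
#'
#' @param affinity symmetric nonnegative N x N matrix.
#' @param nDims number of diffusion coordinates (< N).
#' @param diffusionTime nonnegative integer power applied to the
#'   eigenvalue scaling.
#' @param neuronFactors optional N x rank nonnegative loadings carried
#'   into the result.
#' @param ids optional neuron ids.
#' @return an \linkS4class{EncodingManifold}.
#' @export
diffusionEmbedding <- function(affinity, nDims = 3L, diffusionTime = 1L,
                               neuronFactors = NULL, ids = NULL) {
  W <- as.matrix(affinity)
  N <- nrow(W)
  stopIfNot(N == ncol(W), "affinity must be square")
  stopIfNot(max(abs(W - t(W))) < 1e-8, "affinity must be symmetric")
  stopIfNot(all(W >= 0), "affinity must be nonnegative")
  stopIfNot(nDims >= 1 && nDims < N, "nDims must satisfy 1 <= nDims < N")
  deg <- rowSums(W)
  stopIfNot(all(deg > 0), "every node needs positive degree")

  g <- igraph::graph_from_adjacency_matrix(W > 1e-12, mode = "undirected",
                                           diag = FALSE)
  comp <- as.integer(igraph::components(g)$membership)

  dhalf <- sqrt(deg)
  S <- W / outer(dhalf, dhalf)
  v0 <- dhalf / sqrt(sum(deg))
  S <- S - outer(v0, v0)               # deflate the trivial eigenvector
  eig <- eigen(S, symmetric = TRUE)
  lam <- pmin(eig$values, 1)
  avail <- which(lam > 1e-12)
  if (length(avail) == 0L)
    stop("dimension error: no positive nontrivial eigenvalues", call. = FALSE)
  if (length(avail) < nDims) {
    warning(sprintf(
      "only %d positive nontrivial eigenvalues available; reducing nDims",
      length(avail)))
    nDims <- length(avail)
  }
  keep <- avail[seq_len(nDims)]
  lam <- lam[keep]
  psi <- eig$vectors[, keep, drop = FALSE] / dhalf   # right eigenvectors
  # unit-norm columns: makes coordinates invariant to affinity rescaling
  psi <- sweep(psi, 2L, sqrt(colSums(psi^2)), "/")
  for (m in seq_len(ncol(psi))) {
    i <- which.max(abs(psi[, m]))
    if (psi[i, m] < 0) psi[, m] <- -psi[, m]
  }
  coordsM <- sweep(psi, 2L, lam^diffusionTime, "*")

  if (is.null(neuronFactors)) neuronFactors <- matrix(0, N, 0)
  if (is.null(ids)) ids <- sprintf("n%03d", seq_len(N))
  new("EncodingManifold", embedding = coordsM,
      neuronFactors = as.matrix(neuronFactors),
      eigenvalues = lam, graphDegree = deg, component = comp,
      neuronIds = as.character(ids))
}

#' Build an encoding manifold from a response tensor
#'
#' Full encoding pipeline: normalize the tensor per neuron, factorize it
#' with nonnegative CP (\code{\link{ntfDecompose}}), build the adaptive
#' similarity graph on neuron loadings, and embed with diffusion maps.
#' All-zero neurons are excluded from the embedding.
#'
#' @param tensor a \linkS4class{ResponseTensor}.
#' @param rank CP rank, or \code{"auto"} for the elbow rule
#'   (\code{\link{selectRank}}).
#' @param nDims embedding dimension.
#' @param k local-scale neighbor index for the graph.
#' @param nRestarts,seed passed to the factorization.
#' @param normalization passed to \code{\link{encodingTensor}}.
#' @return an \linkS4class{EncodingManifold} (factors and embedding for
#'   the non-zero neurons).
#' @export
buildEncodingManifold <- function(tensor, rank = "auto", nDims = 3L, k = 7L,
                                  nRestarts = 3L, seed = 1L,
                                  normalization = "per-neuron-max") {
  et <- encodingTensor(tensor, normalization)
  keep <- !(et$neuronIds %in% et$zeroNeurons)
  vals <- et$values[keep, , , drop = FALSE]
  if (identical(rank, "auto"))
    rank <- selectRank(vals, nRestarts = max(1L, nRestarts - 1L),
                       seed = seed)$rank
  fac <- ntfDecompose(vals, rank, nRestarts = nRestarts, seed = seed)
  A <- neuronSimilarityGraph(fac$neuronFactors, k = k)
  diffusionEmbedding(A, nDims = nDims, diffusionTime = 1L,
                     neuronFactors = fac$neuronFactors,
                     ids = et$neuronIds[keep])
}

#' Topology summary of an encoding manifold
#'
#' Quantifies whether the manifold is clustered (retina-like) or
#' continuous (cortex-like): the number of connected components of the
#' k-nearest-neighbor graph on the embedding, a cluster-gap ratio (mean
#' nearest-neighbor distance between k-means clusters over mean
#' within-cluster nearest-neighbor distance; large for well-separated
#' clusters), and, when planted labels are supplied, the adjusted Rand
#' index between those labels and the k-means clustering. The k-means k
#' is chosen by mean silhouette width over 2..\code{maxClusters}.
#'
#' @param manifold an \linkS4class{EncodingManifold} (or bare coordinate
#'   matrix).
#' @param labels optional per-neuron class labels.
#' @param knn neighbor count for the connectivity graph.
#' @param maxClusters largest k-means k considered.
#' @param seed k-means seed.
#' @return list with \code{nComponents}, \code{gapRatio}, \code{labelARI}
#'   (NA without labels), \code{clusters}, \code{kChosen}.
#' @export
topologyStats <- function(manifold, labels = NULL, knn = 10L,
                          maxClusters = 8L, seed = 1L) {
  X <- if (is(manifold, "EncodingManifold")) embedding(manifold)
       else as.matrix(manifold)
  N <- nrow(X)
  if (N < 3L)
    stop("too-few-points error: topology statistics need at least 3 points",
         call. = FALSE)
  d <- sqrt(crossdist2(X, X))
  knn <- min(knn, N - 1L)
  adj <- matrix(FALSE, N, N)
  for (i in seq_len(N)) {
    nb <- order(d[i, ])[2:(knn + 1L)]
    adj[i, nb] <- TRUE
  }
  adj <- adj | t(adj)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  nComponents <- igraph::components(g)$no

  ks <- 2:min(maxClusters, N - 1L)
  best <- NULL
  withSeed(seed, {
    for (k in ks) {
      # duplicate points (e.g. exactly-typed populations) make
      # Hartigan-Wong report spurious non-convergence; harmless here
      km <- suppressWarnings(kmeans(X, centers = k, nstart = 10L,
                                    iter.max = 100L))
      sil <- cluster::silhouette(km$cluster, dmatrix = d)
      w <- mean(sil[, "sil_width"])
      if (is.null(best) || w > best$width)
        best <- list(width = w, clusters = km$cluster, k = k)
    }
  })
  cl <- best$clusters
  diag(d) <- Inf
  within <- between <- rep(NA_real_, N)
  for (i in seq_len(N)) {
    same <- cl == cl[i]; same[i] <- FALSE
    if (any(same)) within[i] <- min(d[i, same])
    if (any(!same & seq_len(N) != i)) between[i] <- min(d[i, cl != cl[i]])
  }
  mw <- mean(within, na.rm = TRUE)
  mb <- mean(between, na.rm = TRUE)
  gapRatio <- if (is.finite(mw) && mw > 0) mb / mw else Inf

  labelARI <- NA_real_
  if (!is.null(labels)) {
    stopIfNot(length(labels) == N, "labels must have one entry per point")
    labelARI <- mclust::adjustedRandIndex(cl, labels)
  }
  list(nComponents = nComponents, gapRatio = gapRatio, labelARI = labelARI,
       clusters = cl, kChosen = best$k)
}
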