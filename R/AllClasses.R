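#' StimulusEnsemble: a parametric stimulus set
#'
#' One row per stimulus sequence: a base class (e.g. grating or a flow
#' pattern), a within-class variant (e.g. spatial frequency), and a drift
#' direction drawn from a regular grid on the circle. Directions are in
#' degrees, counter-clockwise, 0 = rightward drift.
#'
#' @slot sequences data.frame with columns \code{sequence_id},
#'   \code{base_class}, \code{variant_id}, \code{direction}.
#' @slot nDirections integer, number of points on the direction grid.
#' @slot classNames character, the base-class labels in canonical order.
#'
#' @exportClass StimulusEnsemble
setClass("StimulusEnsemble",
  representation(
    sequences   = "data.frame",
    nDirections = "integer",
    classNames  = "character"
  )
)

setValidity("StimulusEnsemble", function(object) {
  sq <- object@sequences
  need <- c("sequence_id", "base_class", "variant_id", "direction")
  miss <- setdiff(need, names(sq))
  if (length(miss) > 0L)
    return(sprintf("sequences is missing column(s): %s",
                   paste(miss, collapse = ", ")))
  if (nrow(sq) == 0L) return("ensemble has no sequences")
  if (anyDuplicated(sq$sequence_id))
    return("sequence_ids are not unique")
  key <- paste(sq$base_class, sq$variant_id, sq$direction, sep = "\r")
  if (anyDuplicated(key))
    return("(base_class, variant_id, direction) triples are not unique")
  if (!all(sq$base_class %in% object@classNames))
    return("sequences contain base classes absent from classNames")
  if (!all(object@classNames %in% sq$base_class))
    return("classNames contains a class with no sequences")
  nd <- object@nDirections
  if (length(nd) != 1L || is.na(nd) || nd < 1L)
    return("nDirections must be a positive integer")
  grid <- directionGrid(nd)
  if (!all(sq$direction %in% grid))
    return(sprintf(
      "all directions must lie on the %d-point grid {%s}",
      nd, paste(grid, collapse = ", ")))
  TRUE
})

#' ResponseTensor: neurons x sequences x time activity
#'
#' The central container: a 3-axis array of nonnegative activity
#' (e.g. PSTHs in arbitrary rate units) for every neuron and stimulus
#' sequence, with uniform time bins. Bin centers start at
#' \code{binWidth/2}, i.e. the first bin begins at stimulus onset.
#'
#' @slot activity numeric array, neurons N x sequences S x time bins T,
#'   finite and nonnegative.
#' @slot binWidth positive numeric, seconds per time bin.
#' @slot ensemble a \linkS4class{StimulusEnsemble} with S entries, row-aligned
#'   with the second axis of \code{activity}.
#' @slot neuronIds character of length N.
#'
#' @exportClass ResponseTensor
setClass("ResponseTensor",
  representation(
    activity  = "array",
    binWidth  = "numeric",
    ensemble  = "StimulusEnsemble",
    neuronIds = "character"
  )
)

setValidity("ResponseTensor", function(object) {
  a <- object@activity
  if (length(dim(a)) != 3L)
    return("activity must be a 3-axis array (neurons x sequences x time)")
  if (dim(a)[1] == 0L) return("tensor has no neurons")
  if (dim(a)[3] == 0L) return("tensor has no time bins")
  bad <- which(!is.finite(a))
  if (length(bad) > 0L) {
    idx <- arrayInd(bad[1L], dim(a))
    return(sprintf(
      "activity contains a non-finite value at (neuron %d, sequence %d, bin %d)",
      idx[1], idx[2], idx[3]))
  }
  neg <- which(a < 0)
  if (length(neg) > 0L) {
    idx <- arrayInd(neg[1L], dim(a))
    return(sprintf(
      "activity contains a negative value at (neuron %d, sequence %d, bin %d)",
      idx[1], idx[2], idx[3]))
  }
  if (dim(a)[2] != nrow(object@ensemble@sequences))
    return(sprintf("sequence axis (%d) does not match ensemble size (%d)",
                   dim(a)[2], nrow(object@ensemble@sequences)))
  if (dim(a)[1] != length(object@neuronIds))
    return(sprintf("neuron axis (%d) does not match neuronIds length (%d)",
                   dim(a)[1], length(object@neuronIds)))
  if (anyDuplicated(object@neuronIds)) return("neuronIds are not unique")
  if (length(object@binWidth) != 1L || !is.finite(object@binWidth) ||
      object@binWidth <= 0)
    return("binWidth must be a single positive number")
  TRUE
})

#' PSTHGrid: direction x time responses of one neuron
#'
#' The PSTHs of a single neuron to one (base class, variant) pattern
#' drifting in every direction, stacked as an image with direction rows
#' in ascending degrees and time columns.
#'
#' @slot matrix numeric, directions x time, nonnegative.
#' @slot directions numeric, ascending degrees, one per row.
#' @slot neuron,baseClass,variant character identifiers of the slice.
#' @slot timeAxis numeric, bin centers in seconds.
#'
#' @exportClass PSTHGrid
setClass("PSTHGrid",
  representation(
    matrix     = "matrix",
    directions = "numeric",
    neuron     = "character",
    baseClass  = "character",
    variant    = "character",
    timeAxis   = "numeric"
  )
)

setValidity("PSTHGrid", function(object) {
  if (nrow(object@matrix) != length(object@directions))
    return("row count must equal the number of directions")
  if (is.unsorted(object@directions, strictly = TRUE))
    return("directions must be strictly ascending")
  if (any(object@matrix < 0)) return("PSTH values must be nonnegative")
  if (ncol(object@matrix) != length(object@timeAxis))
    return("column count must equal the number of time bins")
  TRUE
})

#' DecodingManifold: stimuli embedded in neural-activity coordinates
#'
#' One point per analysis unit (a unique sequence, or a class-direction
#' cell after variant averaging), obtained by PCA of time-averaged
#' population activity. The projection (grand mean and rotation) is kept
#' so related data can be mapped into the same space.
#'
#' @slot coords numeric, points P x dims D.
#' @slot pointLabels data.frame with one row per point; always contains
#'   \code{base_class} and \code{direction}, plus \code{sequence_id} under
#'   sequence grouping.
#' @slot explainedVarianceRatio numeric length D, in [0,1], non-increasing.
#' @slot projection list with elements \code{center} (length-N numeric) and
#'   \code{rotation} (N x D matrix) mapping neuron space to the manifold.
#'
#' @exportClass DecodingManifold
setClass("DecodingManifold",
  representation(
    coords                 = "matrix",
    pointLabels            = "data.frame",
    explainedVarianceRatio = "numeric",
    projection             = "list"
  )
)

setValidity("DecodingManifold", function(object) {
  evr <- object@explainedVarianceRatio
  if (ncol(object@coords) != length(evr))
    return("explainedVarianceRatio length must equal embedding dims")
  if (any(evr < -1e-12) || any(evr > 1 + 1e-9))
    return("explained variance ratios must lie in [0, 1]")
  if (any(diff(evr) > 1e-9))
    return("explained variance ratios must be non-increasing")
  if (sum(evr) > 1 + 1e-9)
    return("explained variance ratios must sum to at most 1")
  if (nrow(object@pointLabels) != nrow(object@coords))
    return("pointLabels must have one row per point")
  TRUE
})

#' TrajectorySet: labeled time-indexed trajectories in a reduced space
#'
#' @slot trajectories numeric array, trajectories K x time T x dims D.
#' @slot labels data.frame, one row per trajectory; contains
#'   \code{base_class} (and optionally \code{direction}).
#' @slot timeAxis numeric length T, bin centers (seconds, or abstract steps).
#' @slot projection list; for PCA-derived sets, \code{center},
#'   \code{rotation} and \code{explainedVarianceRatio} of the pooled
#'   time-point PCA. Empty for directly generated bundles.
#'
#' @exportClass TrajectorySet
setClass("TrajectorySet",
  representation(
    trajectories = "array",
    labels       = "data.frame",
    timeAxis     = "numeric",
    projection   = "list"
  )
)

setValidity("TrajectorySet", function(object) {
  tr <- object@trajectories
  if (length(dim(tr)) != 3L)
    return("trajectories must be a 3-axis array (K x T x D)")
  if (any(!is.finite(tr)))
    return("trajectories contain non-finite values")
  if (nrow(object@labels) != dim(tr)[1])
    return("labels must have one row per trajectory")
  if (!("base_class" %in% names(object@labels)))
    return("labels must contain a base_class column")
  if (length(object@timeAxis) != dim(tr)[2])
    return("timeAxis length must equal the number of time steps")
  TRUE
})

#' EncodingManifold: neurons embedded in stimulus-response coordinates
#'
#' Diffusion-map embedding of neurons from their nonnegative tensor-factor
#' loadings; nearby neurons respond similarly across the stimulus ensemble.
#'
#' @slot embedding numeric, neurons N x dims D (diffusion coordinates).
#' @slot neuronFactors numeric, N x rank nonnegative loadings.
#' @slot eigenvalues numeric length D in (0, 1], non-increasing.
#' @slot graphDegree numeric length N, row sums of the affinity graph.
#' @slot component integer length N, connected-component label per neuron.
#' @slot neuronIds character length N.
#'
#' @exportClass EncodingManifold
setClass("EncodingManifold",
  representation(
    embedding     = "matrix",
    neuronFactors = "matrix",
    eigenvalues   = "numeric",
    graphDegree   = "numeric",
    component     = "integer",
    neuronIds     = "character"
  )
)

setValidity("EncodingManifold", function(object) {
  if (any(object@neuronFactors < 0))
    return("neuronFactors must be nonnegative")
  ev <- object@eigenvalues
  if (length(ev) != ncol(object@embedding))
    return("eigenvalues length must equal embedding dims")
  if (length(ev) > 1L && any(diff(ev) > 1e-9))
    return("eigenvalues must be non-increasing")
  if (any(ev <= 0) || any(ev > 1 + 1e-9))
    return("eigenvalues must lie in (0, 1]")
  n <- nrow(object@embedding)
  if (nrow(object@neuronFactors) != n ||
      length(object@graphDegree) != n ||
      length(object@component) != n ||
      length(object@neuronIds) != n)
    return("per-neuron slots must agree on the number of neurons")
  if (any(object@graphDegree <= 0))
    return("graphDegree must be positive")
  TRUE
})

#' TubularityScores: tightness and crossings of a trajectory bundle set
#'
#' @slot sTight numeric in [0,1]; 1 means zero within-bundle dispersion
#'   against separated bundle centroids.
#' @slot sCross nonnegative numeric; crossing events per cross-class
#'   trajectory pair per time step (at most 1 under this normalization).
#' @slot perClassTightness named numeric, one tightness value per class.
#' @slot perTimeTightness numeric length T, tightness profile over time.
#' @slot perTimeCrossings numeric length T-1, crossing events per pair at
#'   each consecutive step.
#' @slot nTrajectories named integer, trajectories per class.
#' @slot dims integer, dimension of the trajectory space scored.
#'
#' @exportClass TubularityScores
setClass("TubularityScores",
  representation(
    sTight            = "numeric",
    sCross            = "numeric",
    perClassTightness = "numeric",
    perTimeTightness  = "numeric",
    perTimeCrossings  = "numeric",
    nTrajectories     = "integer",
    dims              = "integer"
  )
)

setValidity("TubularityScores", function(object) {
  if (object@sTight < -1e-9 || object@sTight > 1 + 1e-9)
    return("sTight must lie in [0, 1]")
  if (object@sCross < 0) return("sCross must be nonnegative")
  pc <- object@perClassTightness
  if (length(pc) > 0L && (any(pc < -1e-9) || any(pc > 1 + 1e-9)))
    return("per-class tightness values must lie in [0, 1]")
  w <- object@nTrajectories[names(pc)]
  if (length(pc) > 0L &&
      abs(sum(pc * w) / sum(w) - object@sTight) > 1e-6)
    return("per-class tightness must average (trajectory-weighted) to sTight")
  TRUE
})

#' AlignmentReport: the four-metric representational alignment battery
#'
#' RSA, CCA, linear predictivity (directional; both directions stored and
#' averaged) and DSA between two systems responding to a shared stimulus
#' set, plus their arithmetic mean.
#'
#' @slot rsa numeric in [-1,1].
#' @slot cca numeric in [0,1].
#' @slot lp numeric in [-1,1], mean of \code{lpXY} and \code{lpYX}.
#' @slot lpXY,lpYX numeric, linear predictivity X to Y and Y to X.
#' @slot dsa numeric in [0,1].
#' @slot meanScore numeric, arithmetic mean of rsa, cca, lp, dsa.
#' @slot config list of parameters and seeds used.
#'
#' @exportClass AlignmentReport
setClass("AlignmentReport",
  representation(
    rsa       = "numeric",
    cca       = "numeric",
    lp        = "numeric",
    lpXY      = "numeric",
    lpYX      = "numeric",
    dsa       = "numeric",
    meanScore = "numeric",
    config    = "list"
  )
)

setValidity("AlignmentReport", function(object) {
  scores <- c(object@rsa, object@cca, object@lp, object@dsa)
  if (abs(object@meanScore - mean(scores)) > 1e-9)
    return("meanScore must equal the arithmetic mean of rsa, cca, lp, dsa")
  if (abs(object@lp - mean(c(object@lpXY, object@lpYX))) > 1e-9)
    return("lp must be the mean of its two directions")
  TRUE
})
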