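#' @rdname ResponseTensor-class
#' @export
setMethod("activity", "ResponseTensor", function(x) x@activity)

#' @rdname ResponseTensor-class
#' @export
setMethod("ensemble", "ResponseTensor", function(x) x@ensemble)

#' @rdname ResponseTensor-class
#' @export
setMethod("neuronIds", "ResponseTensor", function(x) x@neuronIds)

#' @rdname ResponseTensor-class
#' @export
setMethod("binWidth", "ResponseTensor", function(x) x@binWidth)

#' @rdname ResponseTensor-class
#' @export
setMethod("timeAxis", "ResponseTensor", function(x) {
  T <- dim(x@activity)[3]
  (seq_len(T) - 0.5) * x@binWidth
})

#' @rdname StimulusEnsemble-class
#' @export
setMethod("sequenceTable", "StimulusEnsemble", function(x) x@sequences)

#' @rdname StimulusEnsemble-class
#' @export
setMethod("nDirections", "StimulusEnsemble", function(x) x@nDirections)

#' @rdname StimulusEnsemble-class
#' @export
setMethod("classNames", "StimulusEnsemble", function(x) x@classNames)

#' @rdname StimulusEnsemble-class
#' @export
setMethod("length", "StimulusEnsemble", function(x) nrow(x@sequences))

#' @rdname DecodingManifold-class
#' @export
setMethod("coords", "DecodingManifold", function(x) x@coords)

#' @rdname DecodingManifold-class
#' @export
setMethod("pointLabels", "DecodingManifold", function(x) x@pointLabels)

#' @rdname DecodingManifold-class
#' @export
setMethod("explainedVariance", "DecodingManifold",
          function(x) x@explainedVarianceRatio)

#' @rdname DecodingManifold-class
#' @export
setMethod("projection", "DecodingManifold", function(x) x@projection)

#' @rdname TrajectorySet-class
#' @export
setMethod("trajectories", "TrajectorySet", function(x) x@trajectories)

#' @rdname TrajectorySet-class
#' @export
setMethod("trajectoryLabels", "TrajectorySet", function(x) x@labels)

#' @rdname TrajectorySet-class
#' @export
setMethod("timeAxis", "TrajectorySet", function(x) x@timeAxis)

#' @rdname TrajectorySet-class
#' @export
setMethod("projection", "TrajectorySet", function(x) x@projection)

#' @rdname TrajectorySet-class
#' @export
setMethod("length", "TrajectorySet", function(x) dim(x@trajectories)[1])

#' @rdname EncodingManifold-class
#' @export
setMethod("embedding", "EncodingManifold", function(x) x@embedding)

#' @rdname EncodingManifold-class
#' @export
setMethod("neuronFactors", "EncodingManifold", function(x) x@neuronFactors)

#' @rdname EncodingManifold-class
#' @export
setMethod("neuronIds", "EncodingManifold", function(x) x@neuronIds)

#' @rdname TubularityScores-class
#' @export
setMethod("sTight", "TubularityScores", function(x) x@sTight)

#' @rdname TubularityScores-class
#' @export
setMethod("sCross", "TubularityScores", function(x) x@sCross)

#' @rdname AlignmentReport-class
#' @export
setMethod("meanScore", "AlignmentReport", function(x) x@meanScore)

setMethod("show", "StimulusEnsemble", function(object) {
  sq <- object@sequences
  cat(sprintf(
    "StimulusEnsemble: %d sequences, %d classes x %d variants x %d directions\n",
    nrow(sq), length(object@classNames),
    length(unique(paste(sq$base_class, sq$variant_id))), object@nDirections))
  cat("  classes:", paste(object@classNames, collapse = ", "), "\n")
})

setMethod("show", "ResponseTensor", function(object) {
  d <- dim(object@activity)
  cat(sprintf(
    "ResponseTensor: %d neurons x %d sequences x %d time bins (%.3g s bins)\n",
    d[1], d[2], d[3], object@binWidth))
  cat(sprintf("  activity range [%.4g, %.4g]\n",
              min(object@activity), max(object@activity)))
})

setMethod("show", "PSTHGrid", function(object) {
  cat(sprintf("PSTHGrid: neuron %s, class %s, variant %s (%d directions x %d bins)\n",
              object@neuron, object@baseClass, object@variant,
              nrow(object@matrix), ncol(object@matrix)))
})

setMethod("show", "DecodingManifold", function(object) {
  cat(sprintf("DecodingManifold: %d points in %d dims\n",
              nrow(object@coords), ncol(object@coords)))
  cat(sprintf("  explained variance: %s\n",
              paste(sprintf("%.3f", object@explainedVarianceRatio),
                    collapse = " ")))
})

setMethod("show", "TrajectorySet", function(object) {
  d <- dim(object@trajectories)
  cat(sprintf("TrajectorySet: %d trajectories x %d steps x %d dims\n",
              d[1], d[2], d[3]))
  tab <- table(object@labels$base_class)
  cat("  classes:", paste(sprintf("%s(%d)", names(tab), tab),
                          collapse = ", "), "\n")
})

setMethod("show", "EncodingManifold", function(object) {
  cat(sprintf("EncodingManifold: %d neurons in %d diffusion dims (rank %d factors)\n",
              nrow(object@embedding), ncol(object@embedding),
              ncol(object@neuronFactors)))
  cat(sprintf("  components: %d; eigenvalues: %s\n",
              length(unique(object@component)),
              paste(sprintf("%.3f", object@eigenvalues), collapse = " ")))
})

setMethod("show", "TubularityScores", function(object) {
  cat(sprintf("TubularityScores: S_tight = %.4f, S_cross = %.4f\n",
              object@sTight, object@sCross))
  if (length(object@perClassTightness) > 0L)
    cat("  per-class tightness:",
        paste(sprintf("%s=%.3f", names(object@perClassTightness),
                      object@perClassTightness), collapse = ", "), "\n")
})

setMethod("show", "AlignmentReport", function(object) {
  cat("AlignmentReport\n")
  cat(sprintf("  RSA  %.4f\n  CCA  %.4f\n  LP   %.4f (X->Y %.4f, Y->X %.4f)\n  DSA  %.4f\n",
              object@rsa, object@cca, object@lp, object@lpXY,
              object@lpYX, object@dsa))
  cat(sprintf("  mean %.4f\n", object@meanScore))
})
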