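#' @rdname ResponseTensor-class
#' @param object,x an object of the documented class
#' @export
setGeneric("activity", function(x) standardGeneric("activity"))

#' @rdname ResponseTensor-class
#' @export
setGeneric("ensemble", function(x) standardGeneric("ensemble"))

#' @rdname ResponseTensor-class
#' @export
setGeneric("neuronIds", function(x) standardGeneric("neuronIds"))

#' @rdname ResponseTensor-class
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))

#' @rdname ResponseTensor-class
#' @export
setGeneric("timeAxis", function(x) standardGeneric("timeAxis"))

#' @rdname StimulusEnsemble-class
#' @export
setGeneric("sequenceTable", function(x) standardGeneric("sequenceTable"))

#' @rdname StimulusEnsemble-class
#' @export
setGeneric("nDirections", function(x) standardGeneric("nDirections"))

#' @rdname StimulusEnsemble-class
#' @export
setGeneric("classNames", function(x) standardGeneric("classNames"))

#' @rdname DecodingManifold-class
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname DecodingManifold-class
#' @export
setGeneric("pointLabels", function(x) standardGeneric("pointLabels"))

#' @rdname DecodingManifold-class
#' @export
setGeneric("explainedVariance", function(x) standardGeneric("explainedVariance"))

#' @rdname DecodingManifold-class
#' @export
setGeneric("projection", function(x) standardGeneric("projection"))

#' @rdname TrajectorySet-class
#' @export
setGeneric("trajectories", function(x) standardGeneric("trajectories"))

#' @rdname TrajectorySet-class
#' @export
setGeneric("trajectoryLabels", function(x) standardGeneric("trajectoryLabels"))

#' @rdname EncodingManifold-class
#' @export
setGeneric("embedding", function(x) standardGeneric("embedding"))

#' @rdname EncodingManifold-class
#' @export
setGeneric("neuronFactors", function(x) standardGeneric("neuronFactors"))

#' @rdname TubularityScores-class
#' @export
setGeneric("sTight", function(x) standardGeneric("sTight"))

#' @rdname TubularityScores-class
#' @export
setGeneric("sCross", function(x) standardGeneric("sCross"))

#' @rdname AlignmentReport-class
#' @export
setGeneric("meanScore", function(x) standardGeneric("meanScore"))
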