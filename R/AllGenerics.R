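#' @rdname FameExperiment-accessors
#' @export
setGeneric("profileMatrix", function(x) standardGeneric("profileMatrix"))

#' @rdname FameExperiment-accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname FameExperiment-accessors
#' @export
setGeneric("classLabel", function(x) standardGeneric("classLabel"))

#' @rdname FameExperiment-accessors
#' @export
setGeneric("classCode", function(x) standardGeneric("classCode"))

#' @rdname FameExperiment-accessors
#' @export
setGeneric("replicateIndex", function(x) standardGeneric("replicateIndex"))

#' @rdname FameRanking-accessors
#' @export
setGeneric("rankedFeatures", function(x) standardGeneric("rankedFeatures"))

#' @rdname FameRanking-accessors
#' @export
setGeneric("gainRatios", function(x) standardGeneric("gainRatios"))

#' @rdname FameEmbedding-accessors
#' @export
setGeneric("coordinates", function(x) standardGeneric("coordinates"))

#' @rdname FameEmbedding-accessors
#' @export
setGeneric("explainedVariance", function(x) standardGeneric("explainedVariance"))
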