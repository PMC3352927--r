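#' @include RcppExports.R
NULL

#' Accessor generics
#'
#' Small accessor generics for the assay data containers. Each returns the
#' corresponding slot; none of them exposes raw slot access to user code.
#'
#' @param object an object of the appropriate class
#' @return the slot value
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))

#' @rdname accessors
#' @export
setGeneric("fps", function(object) standardGeneric("fps"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("edSignal", function(object) standardGeneric("edSignal"))

#' @rdname accessors
#' @export
setGeneric("ofSignal", function(object) standardGeneric("ofSignal"))

#' @rdname accessors
#' @export
setGeneric("ofAmplitude", function(object) standardGeneric("ofAmplitude"))

#' @rdname accessors
#' @export
setGeneric("freqs", function(object) standardGeneric("freqs"))

#' @rdname accessors
#' @export
setGeneric("specPower", function(object) standardGeneric("specPower"))

#' @rdname accessors
#' @export
setGeneric("peaks", function(object) standardGeneric("peaks"))

#' @rdname accessors
#' @export
setGeneric("category", function(object) standardGeneric("category"))

#' @rdname accessors
#' @export
setGeneric("heartRateHz", function(object) standardGeneric("heartRateHz"))

#' @rdname accessors
#' @export
setGeneric("beatsPer15s", function(object) standardGeneric("beatsPer15s"))

#' @rdname accessors
#' @export
setGeneric("nSignificantFreqs", function(object) standardGeneric("nSignificantFreqs"))

#' @rdname accessors
#' @export
setGeneric("isAnalysable", function(object) standardGeneric("isAnalysable"))

#' @rdname accessors
#' @export
setGeneric("maskMatrix", function(object) standardGeneric("maskMatrix"))

#' @rdname accessors
#' @export
setGeneric("embryoLengthPx", function(object) standardGeneric("embryoLengthPx"))

#' @rdname accessors
#' @export
setGeneric("roi", function(object) standardGeneric("roi"))

#' @rdname accessors
#' @export
setGeneric("enclosedAreaPx", function(object) standardGeneric("enclosedAreaPx"))

#' @rdname accessors
#' @export
setGeneric("nEnclosedRegions", function(object) standardGeneric("nEnclosedRegions"))

#' @rdname accessors
#' @export
setGeneric("totalISVs", function(object) standardGeneric("totalISVs"))

#' @rdname accessors
#' @export
setGeneric("completeISVs", function(object) standardGeneric("completeISVs"))

#' @rdname accessors
#' @export
setGeneric("railsFound", function(object) standardGeneric("railsFound"))

#' @rdname accessors
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))

#' @rdname accessors
#' @export
setGeneric("adjustedP", function(object) standardGeneric("adjustedP"))

#' @rdname accessors
#' @export
setGeneric("testStatistic", function(object) standardGeneric("testStatistic"))
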