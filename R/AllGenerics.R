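#' @rdname accessors
#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))

#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname accessors
#' @export
setGeneric("markerInfo", function(x) standardGeneric("markerInfo"))

#' @rdname accessors
#' @export
setGeneric("alleleFreq", function(x) standardGeneric("alleleFreq"))

#' @rdname accessors
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname accessors
#' @export
setGeneric("designMatrix", function(x) standardGeneric("designMatrix"))

#' @rdname fit-accessors
#' @export
setGeneric("markerEffects", function(x) standardGeneric("markerEffects"))

#' @rdname fit-accessors
#' @export
setGeneric("inclusionProb", function(x) standardGeneric("inclusionProb"))

#' @rdname fit-accessors
#' @export
setGeneric("varianceTraces", function(x) standardGeneric("varianceTraces"))

#' @rdname fit-accessors
#' @export
setGeneric("heritability", function(x) standardGeneric("heritability"))
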