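#' @rdname accessors
#' @export
setGeneric("geneExpr", function(x) standardGeneric("geneExpr"))

#' @rdname accessors
#' @export
setGeneric("mirnaExpr", function(x) standardGeneric("mirnaExpr"))

#' @rdname accessors
#' @export
setGeneric("survTime", function(x) standardGeneric("survTime"))

#' @rdname accessors
#' @export
setGeneric("survEvent", function(x) standardGeneric("survEvent"))

#' @rdname accessors
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname accessors
#' @export
setGeneric("omicsValues", function(x) standardGeneric("omicsValues"))

#' @rdname accessors
#' @export
setGeneric("omicsLabel", function(x) standardGeneric("omicsLabel"))

#' @rdname accessors
#' @export
setGeneric("featureIDs", function(x) standardGeneric("featureIDs"))

#' @rdname graph-accessors
#' @export
setGeneric("graphWeights", function(x) standardGeneric("graphWeights"))

#' @rdname graph-accessors
#' @export
setGeneric("convMatrix", function(x) standardGeneric("convMatrix"))

#' @rdname fit-accessors
#' @export
setGeneric("riskScores", function(x, ...) standardGeneric("riskScores"))

#' @rdname fit-accessors
#' @export
setGeneric("lossHistory", function(x) standardGeneric("lossHistory"))
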