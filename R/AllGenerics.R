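#' @rdname ligandIds
#' @export
setGeneric("ligandIds", function(x) standardGeneric("ligandIds"))

#' @rdname logP
#' @export
setGeneric("logP", function(x) standardGeneric("logP"))

#' @rdname logP
#' @export
setGeneric("logP<-", function(x, value) standardGeneric("logP<-"))

#' @rdname hsaPercent
#' @export
setGeneric("hsaPercent", function(x, ...) standardGeneric("hsaPercent"))

#' @rdname computeLogP
#' @export
setGeneric("computeLogP", function(x, ...) standardGeneric("computeLogP"))

#' @rdname aggregateBest
#' @export
setGeneric("aggregateBest", function(x, ...) standardGeneric("aggregateBest"))

#' @rdname rocCurve
#' @export
setGeneric("auc", function(x) standardGeneric("auc"))

#' @rdname rocCurve
#' @export
setGeneric("tprAtZeroFpr", function(x) standardGeneric("tprAtZeroFpr"))
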