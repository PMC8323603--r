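#' @rdname TransitionCounts-class
#' @param object,x a \linkS4class{TransitionCounts} object.
#' @export
setGeneric("ctCounts", function(x) standardGeneric("ctCounts"))

#' @rdname TransitionCounts-class
#' @export
setGeneric("ccCounts", function(x) standardGeneric("ccCounts"))

#' @rdname TransitionCounts-class
#' @export
setGeneric("nReads", function(x) standardGeneric("nReads"))

#' @rdname TransitionCounts-class
#' @export
setGeneric("referenceLength", function(x) standardGeneric("referenceLength"))

#' @rdname TransitionCounts-class
#' @export
setGeneric("alignedBases", function(x) standardGeneric("alignedBases"))

#' @export
#' @rdname damageProportions
setGeneric("damageProportions", function(x) standardGeneric("damageProportions"))

#' @export
#' @rdname meanCoverage
setGeneric("meanCoverage", function(x) standardGeneric("meanCoverage"))

#' @export
#' @rdname predictAccuracy
setGeneric("predictAccuracy",
    function(model, features) standardGeneric("predictAccuracy"))

#' @export
setMethod("ctCounts", "TransitionCounts", function(x) x@ctCounts)

#' @export
setMethod("ccCounts", "TransitionCounts", function(x) x@ccCounts)

#' @export
setMethod("nReads", "TransitionCounts", function(x) x@nReads)

#' @export
setMethod("referenceLength", "TransitionCounts", function(x) x@referenceLength)

#' @export
setMethod("alignedBases", "TransitionCounts", function(x) x@alignedBases)
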