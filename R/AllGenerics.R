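#' @include AllClasses.R
NULL

#' @rdname PeptideSet-class
#' @param x,object a \code{PeptideSet}
#' @export
setGeneric("peptideIds", function(x) standardGeneric("peptideIds"))

#' @rdname PeptideSet-class
#' @export
setGeneric("aaSequences", function(x) standardGeneric("aaSequences"))

#' @rdname PeptideSet-class
#' @export
setGeneric("peptideRoles", function(x) standardGeneric("peptideRoles"))

#' @rdname PeptideSet-class
#' @export
setGeneric("cleavageIndex", function(x) standardGeneric("cleavageIndex"))

#' @rdname PeptideSet-class
#' @export
setGeneric("peptideFamilies", function(x) standardGeneric("peptideFamilies"))

#' @rdname PeptideSet-class
#' @export
setGeneric("helixSpan", function(x) standardGeneric("helixSpan"))

#' @rdname substituteBasic
#' @export
setGeneric("substituteBasic",
           function(x, direction = c("K_TO_R", "R_TO_K"))
             standardGeneric("substituteBasic"))

#' @rdname extractNElement
#' @export
setGeneric("extractNElement",
           function(x, n = 15L) standardGeneric("extractNElement"))

#' @rdname extractNElement
#' @export
setGeneric("extractCElement",
           function(x, upstream = 10L, downstream = 23L)
             standardGeneric("extractCElement"))

#' @rdname HelixProfile-class
#' @param object a \code{HelixProfile}
#' @export
setGeneric("helixAnnotations",
           function(object) standardGeneric("helixAnnotations"))

#' @rdname HelixProfile-class
#' @export
setGeneric("helixFraction", function(object) standardGeneric("helixFraction"))

#' @rdname HelixProfile-class
#' @export
setGeneric("upstreamLength", function(object) standardGeneric("upstreamLength"))

#' @rdname TargetingGrid-class
#' @param object a \code{TargetingGrid}
#' @export
setGeneric("gridCalls", function(object) standardGeneric("gridCalls"))

#' @rdname ClassifierReport-class
#' @param object a \code{ClassifierReport}
#' @export
setGeneric("runAccuracies", function(object) standardGeneric("runAccuracies"))

#' @rdname ClassifierReport-class
#' @export
setGeneric("meanAccuracy", function(object) standardGeneric("meanAccuracy"))

#' @rdname ClassifierReport-class
#' @export
setGeneric("modelCoefficients",
           function(object) standardGeneric("modelCoefficients"))
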