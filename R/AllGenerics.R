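#' Accessors for stecg classes
#'
#' @param x an \linkS4class{EcgRecord}, \linkS4class{EcgAnnotation} or
#'   \linkS4class{EcgReport}.
#' @return The slot contents: a numeric vector for \code{ecgSamples}, a single
#'   number for \code{samplingRate}, a string for \code{leadName} and
#'   \code{recordId}, a data.frame for \code{beatTable}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("ecgSamples", function(x) standardGeneric("ecgSamples"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("leadName", function(x) standardGeneric("leadName"))

#' @rdname accessors
#' @export
setGeneric("recordId", function(x) standardGeneric("recordId"))

#' @rdname accessors
#' @export
setGeneric("beatTable", function(x) standardGeneric("beatTable"))

#' @rdname accessors
#' @export
setMethod("ecgSamples", "EcgRecord", function(x) x@samples)

#' @rdname accessors
#' @export
setMethod("samplingRate", "EcgRecord", function(x) x@fs)

#' @rdname accessors
#' @export
setMethod("leadName", "EcgRecord", function(x) x@lead)

#' @rdname accessors
#' @export
setMethod("recordId", "EcgRecord", function(x) x@recordId)

#' @rdname accessors
#' @export
setMethod("beatTable", "EcgAnnotation", function(x) x@beats)

#' @rdname accessors
#' @export
setMethod("recordId", "EcgReport", function(x) x@recordId)
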