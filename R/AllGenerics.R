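#' @name ivwMR-accessors
#' @title Accessors for ivwMR result objects
#' @description Accessor generics for the estimate containers. Slot access
#'   (`@`) is internal; use these in downstream code.
#' @param x an ivwMR object.
#' @param ... passed to methods.
NULL

#' @rdname ivwMR-accessors
#' @export
setGeneric("estimate", function(x, ...) standardGeneric("estimate"))

#' @rdname ivwMR-accessors
#' @export
setGeneric("stdError", function(x, ...) standardGeneric("stdError"))

#' @rdname ivwMR-accessors
#' @export
setGeneric("pValue", function(x, ...) standardGeneric("pValue"))

#' @rdname ivwMR-accessors
#' @export
setGeneric("confInt", function(x, ...) standardGeneric("confInt"))

#' @rdname ivwMR-accessors
#' @export
setGeneric("modelUsed", function(x, ...) standardGeneric("modelUsed"))

#' @rdname ivwMR-accessors
#' @export
setGeneric("hetStats", function(x, ...) standardGeneric("hetStats"))

#' @rdname ivwMR-accessors
#' @export
setGeneric("nInstruments", function(x, ...) standardGeneric("nInstruments"))

#' @rdname ivwMR-accessors
#' @export
setGeneric("assocTable", function(x, ...) standardGeneric("assocTable"))

#' @rdname ivwMR-accessors
#' @export
setGeneric("keptPairs", function(x, ...) standardGeneric("keptPairs"))

#' @rdname ivwMR-accessors
#' @export
setGeneric("droppedPairs", function(x, ...) standardGeneric("droppedPairs"))

#' @rdname ivwMR-accessors
#' @export
setGeneric("outcomeScale", function(x, ...) standardGeneric("outcomeScale"))

#' @rdname ivwMR-accessors
#' @export
setGeneric("provenance", function(x, ...) standardGeneric("provenance"))
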