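#' @name mantleGRN-accessors
#' @title Accessors for mantleGRN classes
#' @description Accessor generics for the package's S4 classes. Use these
#'   rather than reaching into slots.
#' @param x an object of the documented class.
#' @return See the individual methods.
NULL

#' @rdname mantleGRN-accessors
#' @export
setGeneric("valueKind", function(x) standardGeneric("valueKind"))

#' @rdname mantleGRN-accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname mantleGRN-accessors
#' @export
setGeneric("sampleDesign", function(x) standardGeneric("sampleDesign"))

#' @rdname mantleGRN-accessors
#' @export
setGeneric("clusterAssignment", function(x) standardGeneric("clusterAssignment"))

#' @rdname mantleGRN-accessors
#' @export
setGeneric("clusterIds", function(x) standardGeneric("clusterIds"))

#' @rdname mantleGRN-accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname mantleGRN-accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname mantleGRN-accessors
#' @export
setGeneric("keptEdges", function(x) standardGeneric("keptEdges"))

#' @rdname mantleGRN-accessors
#' @export
setGeneric("miThreshold", function(x) standardGeneric("miThreshold"))

#' @rdname mantleGRN-accessors
#' @export
setGeneric("moduleNodes", function(x) standardGeneric("moduleNodes"))

#' @rdname mantleGRN-accessors
#' @export
setGeneric("anchorNodes", function(x) standardGeneric("anchorNodes"))

#' @rdname mantleGRN-accessors
#' @export
setGeneric("hubNodes", function(x) standardGeneric("hubNodes"))

#' @rdname mantleGRN-accessors
#' @export
setGeneric("truthNetwork", function(x) standardGeneric("truthNetwork"))

#' @rdname mantleGRN-accessors
#' @export
setGeneric("markerGenes", function(x) standardGeneric("markerGenes"))

#' @rdname mantleGRN-accessors
#' @export
setGeneric("geneAnnotations", function(x) standardGeneric("geneAnnotations"))

#' @rdname mantleGRN-accessors
#' @export
setGeneric("damageGenes", function(x) standardGeneric("damageGenes"))
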