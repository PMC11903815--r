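#' Resolve one batch of items to annotation records
#'
#' The workhorse of the \linkS4class{AnnotationResolver} contract: given at
#' most \code{batchSize} items, return a named list with one record per
#' item found — \code{list(ec = <character>, taxonId = <integer or NA>,
#' ko = <character>)}. Items without annotation are absent from the result;
#' they are not errors.
#'
#' @param resolver an \linkS4class{AnnotationResolver}.
#' @param items character vector of peptides or accessions.
#' @return named list of annotation records.
#' @export
setGeneric("resolveBatch", function(resolver, items)
    standardGeneric("resolveBatch"))

#' @rdname accessors
#' @export
setGeneric("mapId", function(x) standardGeneric("mapId"))

#' @rdname accessors
#' @export
setGeneric("pathwayName", function(x) standardGeneric("pathwayName"))

#' @rdname accessors
#' @export
setGeneric("pathwayCategory", function(x) standardGeneric("pathwayCategory"))

#' @rdname accessors
#' @export
setGeneric("pathwayNodes", function(x) standardGeneric("pathwayNodes"))

#' @rdname accessors
#' @export
setGeneric("pathwayEdges", function(x) standardGeneric("pathwayEdges"))

#' @rdname accessors
#' @export
setGeneric("groupTable", function(x) standardGeneric("groupTable"))

#' @rdname accessors
#' @export
setGeneric("entryTable", function(x) standardGeneric("entryTable"))

#' @rdname accessors
#' @export
setGeneric("analysisMode", function(x) standardGeneric("analysisMode"))

#' @rdname accessors
#' @export
setGeneric("pathwayMatchCounts", function(x) standardGeneric("pathwayMatchCounts"))

#' @rdname accessors
#' @export
setGeneric("pathwayList", function(x) standardGeneric("pathwayList"))

#' @rdname accessors
#' @export
setGeneric("taxonTable", function(x) standardGeneric("taxonTable"))
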