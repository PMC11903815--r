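#' Accessors for MetaPathDA classes
#'
#' Small read-only accessors so user code never reaches into slots.
#'
#' @param x a \linkS4class{PathwayGraph}, \linkS4class{SampleGroupSet},
#'   \linkS4class{MappingIndex} or \linkS4class{Taxonomy}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("mapId", "PathwayGraph", function(x) x@mapId)

#' @rdname accessors
#' @export
setMethod("pathwayName", "PathwayGraph", function(x) x@name)

#' @rdname accessors
#' @export
setMethod("pathwayCategory", "PathwayGraph", function(x) x@category)

#' @rdname accessors
#' @export
setMethod("pathwayNodes", "PathwayGraph", function(x) x@nodes)

#' @rdname accessors
#' @export
setMethod("pathwayEdges", "PathwayGraph", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("groupTable", "SampleGroupSet", function(x) x@groups)

#' @rdname accessors
#' @export
setMethod("entryTable", "SampleGroupSet", function(x) x@entries)

#' @rdname accessors
#' @export
setMethod("analysisMode", "SampleGroupSet", function(x) x@mode)

#' @rdname accessors
#' @export
setMethod("analysisMode", "MappingIndex", function(x) x@groupSet@mode)

#' @rdname accessors
#' @export
setMethod("groupTable", "MappingIndex", function(x) x@groupSet@groups)

#' @rdname accessors
#' @export
setMethod("entryTable", "MappingIndex", function(x) x@groupSet@entries)

#' @rdname accessors
#' @export
setMethod("pathwayMatchCounts", "MappingIndex", function(x) x@pathwayMatchCounts)

#' @rdname accessors
#' @export
setMethod("pathwayList", "MappingIndex", function(x) x@pathways)

#' @rdname accessors
#' @export
setMethod("taxonTable", "Taxonomy", function(x) x@table)

setMethod("show", "PathwayGraph", function(object) {
    nd <- object@nodes
    cat(sprintf("PathwayGraph %s: %s\n", object@mapId, object@name))
    if (nzchar(object@category))
        cat(sprintf("  category: %s\n", object@category))
    cat(sprintf("  %d nodes (%d enzyme, %d compound, %d maplink), %d edges\n",
                nrow(nd), sum(nd$kind == "enzyme"), sum(nd$kind == "compound"),
                sum(nd$kind == "maplink"), nrow(object@edges)))
})

setMethod("show", "SampleGroupSet", function(object) {
    cat(sprintf("SampleGroupSet (%s mode): %d entries, %d sample(s), %d group(s)\n",
                object@mode, nrow(object@entries),
                length(unique(object@entries$sampleId)), nrow(object@groups)))
    for (i in seq_len(nrow(object@groups)))
        cat(sprintf("  group %d '%s': total %g\n", i,
                    object@groups$name[i], object@groups$totalCount[i]))
})

setMethod("show", "MappingIndex", function(object) {
    cat(sprintf("MappingIndex (%s mode)\n", object@groupSet@mode))
    cat(sprintf("  %d distinct items, %d annotated with >=1 EC\n",
                length(unique(object@groupSet@entries$item)),
                length(object@itemToEcs)))
    cat(sprintf("  %d pathway(s) loaded, %d with >=1 match\n",
                length(object@pathways), sum(object@pathwayMatchCounts > 0)))
})

setMethod("show", "Taxonomy", function(object) {
    cat(sprintf("Taxonomy: %d nodes, root id %s\n", nrow(object@table),
                object@table$taxonId[object@table$taxonId == object@table$parentId][1]))
})

setMethod("show", "FixtureResolver", function(object) {
    cat(sprintf("FixtureResolver (%s mode): %d items, batch size %d%s\n",
                object@mode, length(object@items), object@batchSize,
                if (object@equateIL) ", I/L equated" else ""))
})
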