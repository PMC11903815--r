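#' @import methods
NULL

#' PathwayGraph: a typed metabolic-pathway graph
#'
#' In-memory model of one pathway map parsed from KGML-dialect XML. Nodes
#' are the three element kinds drawn on a map — compounds ("C"-prefixed),
#' enzyme boxes (EC/KO-labelled rectangles) and links to neighbouring maps —
#' and edges are either reactions (compound to compound, catalysed by an
#' enzyme) or map links. Box geometry (centre x/y, width, height; pixel
#' units, y grows downward) is kept verbatim for the SVG overlay renderer.
#'
#' @slot mapId map identifier of the form \code{"map"} + 5 digits.
#' @slot name human-readable pathway title.
#' @slot category top-level pathway class (free-form; used by text filters).
#' @slot nodes data.frame with columns \code{nodeId} (integer),
#'   \code{kind} (\code{"compound"}, \code{"enzyme"} or \code{"maplink"}),
#'   \code{label}, \code{x}, \code{y}, \code{width}, \code{height},
#'   \code{compoundId}, \code{linkedMapId}, and list-columns \code{ec},
#'   \code{ko}, \code{reactions}.
#' @slot edges data.frame with columns \code{from}, \code{to} (node ids),
#'   \code{kind} (\code{"reaction"} or \code{"maplink"}) and
#'   \code{direction} (\code{"directed"} or \code{"bidirectional"}).
#' @export
setClass("PathwayGraph", representation(
    mapId = "character",
    name = "character",
    category = "character",
    nodes = "data.frame",
    edges = "data.frame"
))

setValidity("PathwayGraph", function(object) {
    msgs <- character(0)
    if (!grepl("^map[0-9]{5}$", object@mapId))
        msgs <- c(msgs, sprintf("mapId '%s' is not 'map' + 5 digits", object@mapId))
    nd <- object@nodes
    need <- c("nodeId", "kind", "label", "x", "y", "width", "height",
              "compoundId", "linkedMapId", "ec", "ko", "reactions")
    if (!all(need %in% names(nd)))
        return(paste("nodes is missing columns:",
                     paste(setdiff(need, names(nd)), collapse = ", ")))
    if (anyDuplicated(nd$nodeId))
        msgs <- c(msgs, "duplicate node ids")
    if (!all(nd$kind %in% c("compound", "enzyme", "maplink")))
        msgs <- c(msgs, "unknown node kind")
    geom <- !is.na(nd$width)
    if (any(geom & (nd$width <= 0 | nd$height <= 0)))
        msgs <- c(msgs, "node width/height must be > 0 where present")
    ed <- object@edges
    if (nrow(ed)) {
        if (!all(c(ed$from, ed$to) %in% nd$nodeId))
            msgs <- c(msgs, "edge endpoint refers to a missing node id")
        if (!all(ed$kind %in% c("reaction", "maplink")))
            msgs <- c(msgs, "unknown edge kind")
        ml <- ed$kind == "maplink"
        if (any(ml)) {
            isLink <- nd$nodeId[nd$kind == "maplink"]
            if (!all(ed$from[ml] %in% isLink | ed$to[ml] %in% isLink))
                msgs <- c(msgs, "maplink edge must touch a maplink node")
        }
    }
    if (length(msgs)) msgs else TRUE
})

#' EcLinkTable: EC to pathway/reaction/compound link multimaps
#'
#' Loaded from the two-column link TSV files that connect a full EC number
#' to the pathway maps it occurs on, the reactions ("R" ids) it catalyses
#' and the compounds ("C" ids) it touches.
#'
#' @slot ecToMaps,ecToReactions,ecToCompounds named lists: EC string to a
#'   character vector of target identifiers (set semantics).
#' @export
setClass("EcLinkTable", representation(
    ecToMaps = "list",
    ecToReactions = "list",
    ecToCompounds = "list"
))

setValidity("EcLinkTable", function(object) {
    keys <- c(names(object@ecToMaps), names(object@ecToReactions),
              names(object@ecToCompounds))
    if (length(keys) && !all(isValidEC(keys)))
        "link table keys must be valid EC strings" else TRUE
})

#' SampleGroupSet: grouped samples with their denominators
#'
#' One or two named groups of samples together with every parsed entry.
#' The per-group totals are the denominators of the differential-abundance
#' formulas: in peptide mode the sum of peptide multiplicities, in protein
#' mode the sum of protein abundances, over all member samples.
#'
#' @slot mode \code{"peptide"} or \code{"protein"}.
#' @slot entries data.frame with columns \code{item}, \code{sampleId},
#'   \code{group}, \code{weight} (peptide multiplicity, or 1 per accession)
#'   and \code{abundance} (protein mode; \code{NA} in peptide mode).
#' @slot groups data.frame with columns \code{name} and \code{totalCount},
#'   in upload order (the first row is "group 1" of the formulas).
#' @export
setClass("SampleGroupSet", representation(
    mode = "character",
    entries = "data.frame",
    groups = "data.frame"
))

setValidity("SampleGroupSet", function(object) {
    msgs <- character(0)
    if (!object@mode %in% c("peptide", "protein"))
        msgs <- c(msgs, "mode must be 'peptide' or 'protein'")
    if (anyDuplicated(object@groups$name))
        msgs <- c(msgs, "group names must be unique")
    if (!all(object@entries$group %in% object@groups$name))
        msgs <- c(msgs, "entry assigned to an unknown group")
    # totals must reconcile with the member entries
    for (g in object@groups$name) {
        e <- object@entries[object@entries$group == g, , drop = FALSE]
        tot <- if (object@mode == "peptide") sum(e$weight) else sum(e$abundance)
        want <- object@groups$totalCount[object@groups$name == g]
        if (!isTRUE(all.equal(tot, want)))
            msgs <- c(msgs, sprintf("group '%s' total does not match its entries", g))
    }
    if (length(msgs)) msgs else TRUE
})

#' Taxonomy: a rooted taxonomy tree
#'
#' NCBI-style flat taxonomy: each node has an id, a parent id, a free-form
#' rank and a name. Parent chains terminate at the root, which is its own
#' parent (id 1 in NCBI dumps, but any self-parented node is accepted).
#'
#' @slot table data.frame with columns \code{taxonId}, \code{parentId},
#'   \code{rank}, \code{name}.
#' @export
setClass("Taxonomy", representation(table = "data.frame"))

setValidity("Taxonomy", function(object) {
    tb <- object@table
    need <- c("taxonId", "parentId", "rank", "name")
    if (!all(need %in% names(tb)))
        return(paste("taxonomy table is missing columns:",
                     paste(setdiff(need, names(tb)), collapse = ", ")))
    if (anyDuplicated(tb$taxonId)) return("duplicate taxon ids")
    if (!all(tb$parentId %in% tb$taxonId)) return("parent id missing from table")
    roots <- tb$taxonId[tb$taxonId == tb$parentId]
    if (nrow(tb) && length(roots) != 1L) return("taxonomy must have exactly one root")
    TRUE
})

#' AnnotationResolver: the batch annotation contract
#'
#' Abstract parent for anything that can turn a batch of peptides or
#' UniProtKB accessions into functional/taxonomic annotation records
#' (mirroring batch peptide-info/protein-info JSON endpoints: request
#' \code{\{"peptides": [...]\}} or \code{\{"proteins": [...]\}}, one record
#' per item found, unannotated items absent). Concrete implementations must
#' provide a \code{\link{resolveBatch}} method.
#'
#' @slot batchSize maximum number of items per resolver call.
#' @slot mode \code{"peptide"} or \code{"protein"}.
#' @export
setClass("AnnotationResolver", representation(
    batchSize = "numeric",
    mode = "character",
    "VIRTUAL"
))

#' FixtureResolver: offline table-backed annotation resolver
#'
#' Answers annotation lookups from a TSV-loaded table, standing in for the
#' live batch endpoints so every stage of the pipeline runs offline. In
#' peptide mode, isoleucine/leucine equivalence can be switched on to mimic
#' services that cannot distinguish the two isobaric residues (off by
#' default here).
#'
#' @slot items character vector of known items (uppercase).
#' @slot ec list of character vectors, parallel to \code{items}.
#' @slot taxon integer vector, parallel to \code{items} (\code{NA} = none).
#' @slot ko list of character vectors, parallel to \code{items}.
#' @slot equateIL logical; treat I and L as identical on lookup.
#' @slot calls environment holding \code{n}, the number of batches served
#'   (instrumentation for batching tests and transport accounting).
#' @export
setClass("FixtureResolver", contains = "AnnotationResolver", representation(
    items = "character",
    ec = "list",
    taxon = "integer",
    ko = "list",
    equateIL = "logical",
    calls = "environment"
))

#' MappingIndex: the interlinked item-EC-node-pathway-taxon store
#'
#' Built once per upload; every later interaction (ranking, filtering,
#' per-node comparison, export) reads from it without recomputation. The
#' item-to-pathway relation is exactly the transitive closure
#' item -> EC -> enzyme node -> pathway, with wildcard-aware EC matching.
#'
#' @slot groupSet the \linkS4class{SampleGroupSet} the index was built from.
#' @slot pathways named list of \linkS4class{PathwayGraph} (by map id).
#' @slot linkTable an \linkS4class{EcLinkTable} (possibly empty).
#' @slot itemToEcs named list: item to its annotated EC strings.
#' @slot itemToTaxon named integer: item to taxon id (\code{NA} if none).
#' @slot nodeHits data.frame with columns \code{mapId}, \code{nodeId},
#'   \code{item}: one row per item/enzyme-node match.
#' @slot itemToPathways named list: item to the map ids it reaches.
#' @slot pathwayMatchCounts named numeric over all loaded pathways
#'   (zero-match pathways included): aggregate item weight reaching each
#'   map, each item counted once per pathway.
#' @export
setClass("MappingIndex", representation(
    groupSet = "SampleGroupSet",
    pathways = "list",
    linkTable = "EcLinkTable",
    itemToEcs = "list",
    itemToTaxon = "integer",
    nodeHits = "data.frame",
    itemToPathways = "list",
    pathwayMatchCounts = "numeric"
))

setValidity("MappingIndex", function(object) {
    msgs <- character(0)
    if (!all(names(object@pathwayMatchCounts) %in% names(object@pathways)))
        msgs <- c(msgs, "match counts refer to unloaded pathways")
    if (length(object@pathways) &&
        !setequal(names(object@pathwayMatchCounts), names(object@pathways)))
        msgs <- c(msgs, "every loaded pathway needs a match count (zero allowed)")
    if (any(object@pathwayMatchCounts < 0))
        msgs <- c(msgs, "match counts must be non-negative")
    if (length(msgs)) msgs else TRUE
})
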