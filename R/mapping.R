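#' Build the interlinked item-EC-node-pathway index
#'
#' Constructed once per upload, the index joins every annotated item to the
#' enzyme nodes (and hence pathways) whose EC numbers match its own,
#' wildcard-aware in both directions. An item whose several ECs hit nodes
#' of the same pathway still contributes its weight once to that pathway's
#' match count — pathway counts are per item, not per (item, EC) pair.
#' Item weight is its summed multiplicity across samples in peptide mode
#' and 1 per accession in protein mode (abundances are carried separately
#' for the log2 fold-change view). Items with no EC annotation simply
#' reach no pathway.
#'
#' @param groupSet a \linkS4class{SampleGroupSet}.
#' @param annotations named list from \code{\link{annotateItems}}.
#' @param pathways a \linkS4class{PathwayGraph} or list of them.
#' @param linkTable optional \linkS4class{EcLinkTable}.
#' @return a \linkS4class{MappingIndex}.
#' @export
buildMappingIndex <- function(groupSet, annotations, pathways,
                              linkTable = NULL) {
    stopifnot(is(groupSet, "SampleGroupSet"))
    if (is(pathways, "PathwayGraph")) pathways <- list(pathways)
    names(pathways) <- vapply(pathways, mapId, character(1))
    if (is.null(linkTable)) linkTable <- loadLinkTables()

    itemToEcs <- lapply(annotations, function(a) unique.default(a$ec))
    itemToEcs <- itemToEcs[lengths(itemToEcs) > 0]
    itemToTaxon <- vapply(annotations, function(a)
        if (is.null(a$taxonId)) NA_integer_ else as.integer(a$taxonId), integer(1))
    if (length(itemToTaxon)) names(itemToTaxon) <- names(annotations)

    indices <- lapply(pathways, ecNodeIndex)
    hitMap <- character(0); hitNode <- integer(0); hitItem <- character(0)
    for (it in names(itemToEcs)) {
        for (m in names(pathways)) {
            nodes <- integer(0)
            for (e in itemToEcs[[it]])
                nodes <- c(nodes, ecLookupNodes(indices[[m]], e))
            nodes <- unique.default(nodes)
            if (length(nodes)) {
                hitMap <- c(hitMap, rep(m, length(nodes)))
                hitNode <- c(hitNode, nodes)
                hitItem <- c(hitItem, rep(it, length(nodes)))
            }
        }
    }
    nodeHits <- data.frame(mapId = hitMap, nodeId = hitNode, item = hitItem,
                           stringsAsFactors = FALSE)

    itemToPathways <- lapply(split(nodeHits$mapId, nodeHits$item),
                             function(v) sort(unique(v)))
    weights <- itemWeights(groupSet)
    counts <- stats::setNames(numeric(length(pathways)), names(pathways))
    for (it in names(itemToPathways))
        counts[itemToPathways[[it]]] <-
            counts[itemToPathways[[it]]] + weights[[it]]

    new("MappingIndex", groupSet = groupSet, pathways = pathways,
        linkTable = linkTable, itemToEcs = itemToEcs,
        itemToTaxon = itemToTaxon, nodeHits = nodeHits,
        itemToPathways = itemToPathways, pathwayMatchCounts = counts)
}

# aggregate per-item weight across all samples and groups:
# peptide mode, summed multiplicities; protein mode, 1 per accession
itemWeights <- function(groupSet) {
    e <- groupSet@entries
    if (groupSet@mode == "peptide")
        vapply(split(e$weight, e$item), sum, numeric(1))
    else
        stats::setNames(rep(1, length(unique(e$item))), sort(unique(e$item)))
}

# per-item weight (or abundance sum) within one group
itemGroupWeight <- function(groupSet, group, abundance = FALSE) {
    e <- groupSet@entries[groupSet@entries$group == group, , drop = FALSE]
    v <- if (abundance) e$abundance else e$weight
    vapply(split(v, e$item), sum, numeric(1))
}

#' Rank pathways by aggregate match count
#'
#' Pathways in descending order of the number of items (weighted) mapped to
#' them, aggregated across all uploaded samples; ties break by map id
#' ascending, and zero-match pathways are kept at the tail so the ordered
#' list covers every loaded pathway.
#'
#' @param index a \linkS4class{MappingIndex}.
#' @return data.frame with columns \code{mapId}, \code{name},
#'   \code{category}, \code{count}, in rank order.
#' @export
rankPathways <- function(index) {
    counts <- index@pathwayMatchCounts
    df <- data.frame(
        mapId = names(counts),
        name = vapply(index@pathways[names(counts)], pathwayName, character(1)),
        category = vapply(index@pathways[names(counts)], pathwayCategory,
                          character(1)),
        count = unname(counts),
        stringsAsFactors = FALSE)
    df <- df[order(-df$count, df$mapId, method = "radix"), , drop = FALSE]
    rownames(df) <- NULL
    df
}

#' Filter a ranked pathway list
#'
#' Conjunction of up to three criteria: a case-insensitive substring match
#' over pathway category, map id and name; a set of EC numbers the pathway
#' must contain (as node annotations — content, not user matches;
#' wildcard-aware); and a set of compound ids the pathway must contain.
#' Relative order is preserved; an empty result is legal.
#'
#' @param index a \linkS4class{MappingIndex}.
#' @param ranked optionally, a pre-computed \code{\link{rankPathways}}
#'   result (possibly already filtered); defaults to the full ranking.
#' @param text optional substring query.
#' @param requiredEcs optional character vector of EC numbers (all must be
#'   present in the pathway).
#' @param requiredCompounds optional character vector of "C" ids.
#' @return the filtered ranking data.frame.
#' @export
filterPathways <- function(index, ranked = rankPathways(index), text = NULL,
                           requiredEcs = NULL, requiredCompounds = NULL) {
    keep <- rep(TRUE, nrow(ranked))
    if (!is.null(text) && nzchar(text)) {
        hay <- tolower(paste(ranked$category, ranked$mapId, ranked$name))
        keep <- keep & vapply(hay, function(h)
            grepl(tolower(text), h, fixed = TRUE), logical(1), USE.NAMES = FALSE)
    }
    if (!is.null(requiredEcs) && length(requiredEcs)) {
        keep <- keep & vapply(ranked$mapId, function(m) {
            idx <- ecNodeIndex(index@pathways[[m]])
            all(vapply(requiredEcs, function(e)
                length(ecLookupNodes(idx, e)) > 0, logical(1)))
        }, logical(1), USE.NAMES = FALSE)
    }
    if (!is.null(requiredCompounds) && length(requiredCompounds)) {
        keep <- keep & vapply(ranked$mapId, function(m) {
            nd <- index@pathways[[m]]@nodes
            all(requiredCompounds %in% nd$compoundId[nd$kind == "compound"])
        }, logical(1), USE.NAMES = FALSE)
    }
    out <- ranked[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Filter options that lead to at least one result
#'
#' The EC and compound filter choices offered to a user: exactly those
#' values that, applied alone, retain at least one pathway — i.e. the union
#' of node ECs and compound ids over the loaded pathways.
#'
#' @param index a \linkS4class{MappingIndex}.
#' @return list with sorted character vectors \code{ec} and \code{compound}.
#' @export
availableFilterOptions <- function(index) {
    ecs <- character(0); cpds <- character(0)
    for (p in index@pathways) {
        nd <- p@nodes
        ecs <- c(ecs, unlist(nd$ec[nd$kind == "enzyme"], use.names = FALSE))
        cpds <- c(cpds, nd$compoundId[nd$kind == "compound"])
    }
    list(ec = sort(unique(ecs)), compound = sort(unique(cpds[!is.na(cpds)])))
}

#' Summarize the taxonomy of one pathway node
#'
#' The lowest common ancestor of the taxon ids of all items matching the
#' node; absent (\code{NULL}) if no matching item carries a taxon. A taxon
#' id missing from the loaded taxonomy is an error naming the id.
#'
#' @param index a \linkS4class{MappingIndex}.
#' @param mapId pathway map id.
#' @param nodeId node id within that pathway.
#' @param taxonomy a \linkS4class{Taxonomy}.
#' @return list \code{(taxonId, rank, name)}, or \code{NULL}.
#' @export
nodeTaxonSummary <- function(index, mapId, nodeId, taxonomy) {
    h <- index@nodeHits
    items <- unique(h$item[h$mapId == mapId & h$nodeId == nodeId])
    taxa <- index@itemToTaxon[items]
    taxa <- taxa[!is.na(taxa)]
    if (!length(taxa)) return(NULL)
    taxonInfo(taxonomy, taxonLCA(taxonomy, unname(taxa)))
}
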