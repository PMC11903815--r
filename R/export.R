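#' Dense export of the internal mapping store
#'
#' One CSV row per (item, EC, pathway) triple, with the item's sample and
#' group carried along, so downstream tools can re-join everything the
#' analysis knew. Items with no EC annotation, and ECs reaching no
#' pathway, still appear (with empty EC/pathway columns) so the export
#' reconciles with the upload totals. Ordering is deterministic
#' (item, ec, map id, sample ascending, byte order) and quoting is
#' RFC 4180, so re-exporting an identical index is byte-identical.
#'
#' @param index a \linkS4class{MappingIndex}.
#' @param path optional file path; when given the CSV is written there.
#' @return the CSV content as a single string (invisibly when \code{path}
#'   is given).
#' @export
exportDense <- function(index, path = NULL) {
    e <- index@groupSet@entries
    pairs <- unique(e[c("item", "sampleId", "group")])
    idxMemo <- new.env(parent = emptyenv())
    nodeIdx <- function(m) {
        got <- get0(m, envir = idxMemo, inherits = FALSE)
        if (is.null(got)) {
            got <- ecNodeIndex(index@pathways[[m]])
            assign(m, got, envir = idxMemo)
        }
        got
    }
    rows <- list()
    for (i in seq_len(nrow(pairs))) {
        it <- pairs$item[i]
        ecs <- index@itemToEcs[[it]]
        if (is.null(ecs) || !length(ecs)) {
            rows[[length(rows) + 1L]] <- data.frame(
                item = it, sample_id = pairs$sampleId[i], group = pairs$group[i],
                ec = "", map_id = "", pathway_name = "", stringsAsFactors = FALSE)
            next
        }
        maps <- index@itemToPathways[[it]]
        for (ec in ecs) {
            # pathways this particular EC reaches (subset of the item's maps)
            ecMaps <- if (is.null(maps)) character(0) else
                maps[vapply(maps, function(m)
                    length(ecLookupNodes(nodeIdx(m), ec)) > 0,
                    logical(1))]
            if (!length(ecMaps)) {
                rows[[length(rows) + 1L]] <- data.frame(
                    item = it, sample_id = pairs$sampleId[i],
                    group = pairs$group[i], ec = ec, map_id = "",
                    pathway_name = "", stringsAsFactors = FALSE)
            } else {
                rows[[length(rows) + 1L]] <- data.frame(
                    item = it, sample_id = pairs$sampleId[i],
                    group = pairs$group[i], ec = ec, map_id = ecMaps,
                    pathway_name = vapply(index@pathways[ecMaps], pathwayName,
                                          character(1)),
                    stringsAsFactors = FALSE)
            }
        }
    }
    df <- do.call(rbind, rows)
    df <- df[orderC(df$item, df$ec, df$map_id, df$sample_id), , drop = FALSE]
    rownames(df) <- NULL
    csv <- formatCSV(df)
    if (!is.null(path)) return(invisible(writeText(csv, path)))
    csv
}

#' Export the ordered pathway list
#'
#' All loaded pathways in match order — descending aggregate match count,
#' ties broken by map id, zero-match pathways at the tail — as RFC-4180
#' CSV with columns \code{map_id}, \code{name}, \code{category},
#' \code{match_count}.
#'
#' @param ranked a \code{\link{rankPathways}} result.
#' @param path optional output file path.
#' @return CSV content as a single string (invisibly when written).
#' @export
exportPathwayList <- function(ranked, path = NULL) {
    df <- data.frame(map_id = ranked$mapId, name = ranked$name,
                     category = ranked$category, match_count = ranked$count,
                     stringsAsFactors = FALSE)
    csv <- formatCSV(df)
    if (!is.null(path)) return(invisible(writeText(csv, path)))
    csv
}

#' Export a per-node comparison table
#'
#' The \code{\link{comparePathway}} result as CSV; infinite and undefined
#' differential-abundance sentinels serialize as \code{+inf}, \code{-inf}
#' and \code{NA}.
#'
#' @param comparison a \code{\link{comparePathway}} result.
#' @param path optional output file path.
#' @return CSV content as a single string (invisibly when written).
#' @export
exportNodeComparison <- function(comparison, path = NULL) {
    df <- data.frame(node_id = comparison$nodeId, label = comparison$label,
                     x = comparison$x, p1 = comparison$p1,
                     y = comparison$y, p2 = comparison$p2,
                     da_raw = comparison$daRaw, da_normalized = comparison$daNorm,
                     stringsAsFactors = FALSE)
    csv <- formatCSV(df)
    if (!is.null(path)) return(invisible(writeText(csv, path)))
    csv
}
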