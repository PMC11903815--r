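#' Load a taxonomy from a flat TSV
#'
#' NCBI-style flat table with columns \code{taxon_id}, \code{parent_id},
#' \code{rank}, \code{name} (header required, tab-separated). The root is
#' its own parent; every parent chain must terminate at it.
#'
#' @param table TSV content (string or lines) or a file path.
#' @return a \linkS4class{Taxonomy}.
#' @export
loadTaxonomy <- function(table) {
    lines <- if (length(table) == 1L && file.exists(table))
        readLines(table, warn = FALSE) else splitLines(table)
    lines <- lines[nzchar(trimws(lines))]
    f <- strsplit(lines, "\t", fixed = TRUE)
    header <- trimws(f[[1]])
    need <- c("taxon_id", "parent_id", "rank", "name")
    if (!all(need %in% header))
        stop("taxonomy TSV needs columns taxon_id, parent_id, rank, name",
             call. = FALSE)
    j <- match(need, header)
    rows <- f[-1]
    tb <- data.frame(
        taxonId = vapply(rows, function(v) as.integer(v[j[1]]), integer(1)),
        parentId = vapply(rows, function(v) as.integer(v[j[2]]), integer(1)),
        rank = vapply(rows, function(v) trimws(v[j[3]]), character(1)),
        name = vapply(rows, function(v) trimws(v[j[4]]), character(1)),
        stringsAsFactors = FALSE)
    new("Taxonomy", table = tb)
}

#' Lineage and lowest common ancestor in a taxonomy
#'
#' \code{taxonLineage} walks the parent chain from a taxon up to the root
#' (returned root-last is \emph{not} the convention here: the vector runs
#' from the taxon itself up to the root). \code{taxonLCA} returns the
#' deepest node that lies on every given taxon's lineage — the summary
#' used to assign a taxonomic rank and name to a pathway node from the
#' peptides matching it.
#'
#' @param taxonomy a \linkS4class{Taxonomy}.
#' @param taxonId a single taxon id.
#' @param taxonIds one or more taxon ids.
#' @return \code{taxonLineage}: integer vector, taxon first, root last.
#'   \code{taxonLCA}: a single taxon id.
#' @export
taxonLineage <- function(taxonomy, taxonId) {
    tb <- taxonomy@table
    pos <- match(taxonId, tb$taxonId)
    if (is.na(pos))
        stop(sprintf("taxon id %d not found in taxonomy", taxonId), call. = FALSE)
    out <- integer(0)
    cur <- taxonId
    repeat {
        out <- c(out, cur)
        p <- tb$parentId[match(cur, tb$taxonId)]
        if (p == cur) break
        if (length(out) > nrow(tb))
            stop("taxonomy parent chain does not terminate", call. = FALSE)
        cur <- p
    }
    out
}

#' @rdname taxonLineage
#' @export
taxonLCA <- function(taxonomy, taxonIds) {
    taxonIds <- unique.default(taxonIds)
    stopifnot(length(taxonIds) >= 1L)
    lin <- taxonLineage(taxonomy, taxonIds[1])
    for (t in taxonIds[-1]) {
        keep <- lin %in% taxonLineage(taxonomy, t)
        lin <- lin[keep]
    }
    lin[1]   # lineages are ordered deep-to-root, so the first survivor is deepest
}

taxonInfo <- function(taxonomy, taxonId) {
    tb <- taxonomy@table
    i <- match(taxonId, tb$taxonId)
    list(taxonId = taxonId, rank = tb$rank[i], name = tb$name[i])
}
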