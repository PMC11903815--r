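#' Parse a pathway graph from KGML-dialect XML
#'
#' Reads the subset of KEGG's KGML 0.7.x that the pipeline needs: the
#' \code{pathway} root (map number, title, optional \code{category}
#' attribute carrying the top-level pathway class), \code{entry} elements
#' of type \code{enzyme}/\code{ortholog} (EC and KO tokens split on
#' whitespace, \code{"ec:"}/\code{"ko:"} prefixes stripped),
#' \code{compound} (\code{"cpd:"} prefix stripped) and \code{map}
#' (\code{"path:"} prefix stripped), their \code{graphics} boxes
#' (centre x/y, width, height, pixel units, y downward — preserved
#' verbatim), \code{reaction} elements (one reaction edge per
#' substrate/product pair, bidirectional when the reaction is reversible)
#' and \code{relation} elements of type \code{maplink}. Unknown elements
#' and other relation types are ignored (with a message when
#' \code{verbose}), for forward compatibility.
#'
#' An entry without graphics is kept with null geometry and a warning; a
#' reaction or relation endpoint that names no entry is a parse error
#' naming the id.
#'
#' @param xml KGML content as a string, or a file path.
#' @param verbose emit messages about ignored elements.
#' @return a \linkS4class{PathwayGraph}.
#' @seealso \code{\link{writeKGML}} for the inverse.
#' @export
parseKGML <- function(xml, verbose = FALSE) {
    doc <- xml2::read_xml(xml)
    root <- xml2::xml_find_first(doc, "/pathway")
    if (inherits(root, "xml_missing"))
        stop("not a pathway document: no <pathway> root", call. = FALSE)
    rawName <- xml2::xml_attr(root, "name")
    mapid <- sub("^path:", "", rawName %||% "")
    if (grepl("^[a-z]*[0-9]{5}$", mapid) && !grepl("^map", mapid))
        mapid <- paste0("map", sub("^[a-z]*", "", mapid))
    title <- xml2::xml_attr(root, "title") %||% ""
    category <- xml2::xml_attr(root, "category")
    if (is.na(category)) category <- ""

    entries <- xml2::xml_find_all(root, "entry")
    n <- length(entries)
    nodeId <- integer(n); kind <- character(n); label <- character(n)
    x <- y <- w <- h <- rep(NA_real_, n)
    compoundId <- linkedMapId <- rep(NA_character_, n)
    ec <- ko <- reactions <- vector("list", n)
    keep <- logical(n)
    for (i in seq_len(n)) {
        e <- entries[[i]]
        type <- xml2::xml_attr(e, "type")
        id <- as.integer(xml2::xml_attr(e, "id"))
        names_ <- strsplit(trimws(xml2::xml_attr(e, "name") %||% ""), "\\s+")[[1]]
        nodeId[i] <- id
        ec[[i]] <- character(0); ko[[i]] <- character(0); reactions[[i]] <- character(0)
        if (type %in% c("enzyme", "ortholog")) {
            kind[i] <- "enzyme"
            ec[[i]] <- sub("^ec:", "", grep("^ec:", names_, value = TRUE))
            ko[[i]] <- sub("^ko:", "", grep("^ko:", names_, value = TRUE))
            # bare EC tokens (no prefix) are accepted in the dialect
            bare <- names_[!grepl(":", names_)]
            ec[[i]] <- unique(c(ec[[i]], bare[isValidEC(bare)]))
            rx <- trimws(xml2::xml_attr(e, "reaction"))
            if (!is.na(rx) && nzchar(rx))
                reactions[[i]] <- sub("^rn:", "", strsplit(rx, "\\s+")[[1]])
        } else if (type == "compound") {
            kind[i] <- "compound"
            cid <- sub("^cpd:", "", names_[1] %||% "")
            compoundId[i] <- cid
        } else if (type == "map") {
            kind[i] <- "maplink"
            linkedMapId[i] <- sub("^path:", "", names_[1] %||% "")
        } else {
            if (verbose) message(sprintf("ignoring entry %d of type '%s'", id, type))
            next
        }
        keep[i] <- TRUE
        g <- xml2::xml_find_first(e, "graphics")
        if (inherits(g, "xml_missing")) {
            warning(sprintf("entry %d has no graphics; kept with null geometry", id),
                    call. = FALSE)
            label[i] <- ""
        } else {
            x[i] <- as.numeric(xml2::xml_attr(g, "x"))
            y[i] <- as.numeric(xml2::xml_attr(g, "y"))
            w[i] <- as.numeric(xml2::xml_attr(g, "width"))
            h[i] <- as.numeric(xml2::xml_attr(g, "height"))
            lb <- xml2::xml_attr(g, "name")
            label[i] <- if (is.na(lb)) "" else lb
        }
    }
    nodes <- data.frame(nodeId = nodeId[keep], kind = kind[keep],
                        label = label[keep], x = x[keep], y = y[keep],
                        width = w[keep], height = h[keep],
                        compoundId = compoundId[keep],
                        linkedMapId = linkedMapId[keep],
                        stringsAsFactors = FALSE)
    nodes$ec <- ec[keep]; nodes$ko <- ko[keep]; nodes$reactions <- reactions[keep]

    edgeFrom <- integer(0); edgeTo <- integer(0)
    edgeKind <- character(0); edgeDir <- character(0)
    checkEndpoint <- function(id, where) {
        if (!id %in% nodes$nodeId)
            stop(sprintf("dangling %s endpoint: entry id %d is not a node",
                         where, id), call. = FALSE)
        id
    }
    for (r in xml2::xml_find_all(root, "reaction")) {
        rev <- identical(xml2::xml_attr(r, "type"), "reversible")
        subs <- vapply(xml2::xml_find_all(r, "substrate"),
                       function(s) as.integer(xml2::xml_attr(s, "id")), integer(1))
        prods <- vapply(xml2::xml_find_all(r, "product"),
                        function(p) as.integer(xml2::xml_attr(p, "id")), integer(1))
        for (s in subs) for (p in prods) {
            edgeFrom <- c(edgeFrom, checkEndpoint(s, "reaction"))
            edgeTo <- c(edgeTo, checkEndpoint(p, "reaction"))
            edgeKind <- c(edgeKind, "reaction")
            edgeDir <- c(edgeDir, if (rev) "bidirectional" else "directed")
        }
    }
    for (rel in xml2::xml_find_all(root, "relation")) {
        type <- xml2::xml_attr(rel, "type")
        if (!identical(type, "maplink")) {
            if (verbose) message(sprintf("ignoring relation of type '%s'", type))
            next
        }
        e1 <- checkEndpoint(as.integer(xml2::xml_attr(rel, "entry1")), "relation")
        e2 <- checkEndpoint(as.integer(xml2::xml_attr(rel, "entry2")), "relation")
        edgeFrom <- c(edgeFrom, e1); edgeTo <- c(edgeTo, e2)
        edgeKind <- c(edgeKind, "maplink"); edgeDir <- c(edgeDir, "directed")
    }
    edges <- data.frame(from = edgeFrom, to = edgeTo, kind = edgeKind,
                        direction = edgeDir, stringsAsFactors = FALSE)
    new("PathwayGraph", mapId = mapid, name = title, category = category,
        nodes = nodes, edges = edges)
}

#' Serialize a PathwayGraph back to KGML-dialect XML
#'
#' Inverse of \code{\link{parseKGML}} up to graph isomorphism: re-parsing
#' the output yields the same nodes (ids, kinds, labels, annotations,
#' geometry) and the same edge multiset. Reaction edges that share a
#' source enzyme context are written as individual one-substrate/
#' one-product reaction elements, which re-parse to the identical edge set.
#'
#' @param pathway a \linkS4class{PathwayGraph}.
#' @return a single string of XML.
#' @export
writeKGML <- function(pathway) {
    stopifnot(is(pathway, "PathwayGraph"))
    esc <- function(x) {
        x <- gsub("&", "&amp;", x, fixed = TRUE)
        x <- gsub("<", "&lt;", x, fixed = TRUE)
        x <- gsub(">", "&gt;", x, fixed = TRUE)
        gsub('"', "&quot;", x, fixed = TRUE)
    }
    nd <- pathway@nodes
    out <- c(sprintf('<?xml version="1.0"?>'),
             sprintf('<pathway name="path:%s" title="%s" category="%s">',
                     esc(pathway@mapId), esc(pathway@name), esc(pathway@category)))
    num <- function(v) sprintf("%.15g", v)
    for (i in seq_len(nrow(nd))) {
        kindAttr <- switch(nd$kind[i],
            enzyme = "enzyme", compound = "compound", maplink = "map")
        nm <- switch(nd$kind[i],
            enzyme = paste(c(if (length(nd$ec[[i]])) paste0("ec:", nd$ec[[i]]),
                             if (length(nd$ko[[i]])) paste0("ko:", nd$ko[[i]])),
                           collapse = " "),
            compound = paste0("cpd:", nd$compoundId[i]),
            maplink = paste0("path:", nd$linkedMapId[i]))
        rx <- if (nd$kind[i] == "enzyme" && length(nd$reactions[[i]]))
            sprintf(' reaction="%s"',
                    paste(paste0("rn:", nd$reactions[[i]]), collapse = " ")) else ""
        out <- c(out, sprintf('  <entry id="%d" name="%s" type="%s"%s>',
                              nd$nodeId[i], esc(nm), kindAttr, rx))
        if (!is.na(nd$x[i]))
            out <- c(out, sprintf(
                '    <graphics name="%s" x="%s" y="%s" width="%s" height="%s"/>',
                esc(nd$label[i]), num(nd$x[i]), num(nd$y[i]),
                num(nd$width[i]), num(nd$height[i])))
        out <- c(out, "  </entry>")
    }
    ed <- pathway@edges
    rxn <- ed[ed$kind == "reaction", , drop = FALSE]
    for (i in seq_len(nrow(rxn))) {
        type <- if (rxn$direction[i] == "bidirectional") "reversible" else "irreversible"
        out <- c(out,
                 sprintf('  <reaction id="%d" type="%s">', i, type),
                 sprintf('    <substrate id="%d"/>', rxn$from[i]),
                 sprintf('    <product id="%d"/>', rxn$to[i]),
                 "  </reaction>")
    }
    ml <- ed[ed$kind == "maplink", , drop = FALSE]
    for (i in seq_len(nrow(ml)))
        out <- c(out, sprintf('  <relation entry1="%d" entry2="%d" type="maplink"/>',
                              ml$from[i], ml$to[i]))
    paste0(paste(c(out, "</pathway>"), collapse = "\n"), "\n")
}

#' Load EC link tables
#'
#' Aggregates two-column (EC, target id) TSV files into the three multimaps
#' that connect an EC number to the pathway maps, reactions and compounds
#' it is linked to. Duplicate rows collapse (set semantics); a malformed EC
#' key aborts the load naming the row.
#'
#' @param ecToMaps,ecToReactions,ecToCompounds TSV content (string or lines)
#'   or file path; any may be \code{NULL} for an empty map. Lines starting
#'   with \code{#} are comments.
#' @return an \linkS4class{EcLinkTable}.
#' @export
loadLinkTables <- function(ecToMaps = NULL, ecToReactions = NULL,
                           ecToCompounds = NULL) {
    readMap <- function(src) {
        if (is.null(src)) return(list())
        lines <- if (length(src) == 1L && file.exists(src))
            readLines(src, warn = FALSE) else splitLines(src)
        lines <- trimws(lines)
        lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
        if (!length(lines)) return(list())
        f <- strsplit(lines, "\t", fixed = TRUE)
        ecs <- vapply(f, function(v) trimws(v[1]), character(1))
        tgt <- vapply(f, function(v) trimws(v[2] %||% ""), character(1))
        stopIfBadEC(ecs, rows = seq_along(ecs), what = "EC link key")
        lapply(split(tgt, ecs), function(v) sort(unique(v)))
    }
    new("EcLinkTable", ecToMaps = readMap(ecToMaps),
        ecToReactions = readMap(ecToReactions),
        ecToCompounds = readMap(ecToCompounds))
}

#' Index a pathway's enzyme nodes by EC number
#'
#' Every enzyme node appears under each of its EC numbers; compound and
#' maplink nodes are excluded. Use \code{\link{ecLookupNodes}} to query the
#' index with a wildcard-aware EC.
#'
#' @param pathway a \linkS4class{PathwayGraph}.
#' @return named list: EC string to integer vector of node ids.
#' @export
ecNodeIndex <- function(pathway) {
    nd <- pathway@nodes
    enz <- nd[nd$kind == "enzyme", , drop = FALSE]
    idx <- list()
    for (i in seq_len(nrow(enz)))
        for (e in enz$ec[[i]])
            idx[[e]] <- c(idx[[e]], enz$nodeId[i])
    lapply(idx, function(v) sort(unique(v)))
}

#' Query an EC node index with wildcard matching
#'
#' A trailing \code{"-"} in the query (or in a node's own partial EC)
#' matches any value in that and later positions, so querying
#' \code{"2.8.3.-"} returns every node whose EC starts \code{"2.8.3."}.
#'
#' @param index result of \code{\link{ecNodeIndex}}.
#' @param query a single EC string, wildcards allowed.
#' @return sorted integer vector of node ids (possibly empty).
#' @export
ecLookupNodes <- function(index, query) {
    if (!length(index)) return(integer(0))
    hit <- vapply(names(index), function(e) ecMatches(query, e), logical(1))
    sort(unique(unlist(index[hit], use.names = FALSE))) %||% integer(0)
}
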