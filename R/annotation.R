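#' Load an offline table-backed annotation resolver
#'
#' Reads a TSV with columns \code{item}, \code{ec_list}
#' (semicolon-separated EC numbers, trailing-\code{-} wildcards legal),
#' optional \code{taxon_id} and optional \code{ko_list}, and returns a
#' \linkS4class{FixtureResolver} that answers batch lookups from it. Every
#' EC string is checked against the EC grammar at load time; a malformed
#' one aborts the load naming the offending row.
#'
#' @param table TSV content (single string), a character vector of lines,
#'   or a path to a TSV file.
#' @param mode \code{"peptide"} or \code{"protein"}.
#' @param batchSize maximum items per \code{\link{resolveBatch}} call.
#' @param equateIL treat isoleucine and leucine as identical on lookup
#'   (peptide mode; off by default — the live peptide services equate them,
#'   this offline table does only when asked).
#' @return a \linkS4class{FixtureResolver}.
#' @examples
#' r <- loadFixtureResolver("item\tec_list\ttaxon_id\nAAK\t2.3.1.9\t816\n",
#'                          mode = "peptide")
#' resolveBatch(r, "AAK")
#' @export
loadFixtureResolver <- function(table, mode = c("peptide", "protein"),
                                batchSize = 1000, equateIL = FALSE) {
    mode <- match.arg(mode)
    stopifnot(batchSize >= 1)
    lines <- if (length(table) == 1L && file.exists(table))
        readLines(table, warn = FALSE) else splitLines(table)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("empty resolver table", call. = FALSE)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    header <- trimws(fields[[1]])
    if (!"item" %in% header || !"ec_list" %in% header)
        stop("resolver table needs 'item' and 'ec_list' columns", call. = FALSE)
    col <- function(f, name) {
        j <- match(name, header)
        if (is.na(j) || j > length(f)) "" else trimws(f[j])
    }
    items <- character(0); ecs <- list(); tax <- integer(0); kos <- list()
    for (r in seq_along(fields)[-1]) {
        f <- fields[[r]]
        it <- toupper(col(f, "item"))
        if (!nzchar(it)) next
        eclist <- col(f, "ec_list")
        ecv <- if (nzchar(eclist)) trimws(strsplit(eclist, ";", fixed = TRUE)[[1]])
               else character(0)
        ecv <- ecv[nzchar(ecv)]
        stopIfBadEC(ecv, rows = rep(r, length(ecv)), what = "EC")
        tv <- col(f, "taxon_id")
        kolist <- col(f, "ko_list")
        kov <- if (nzchar(kolist)) trimws(strsplit(kolist, ";", fixed = TRUE)[[1]])
               else character(0)
        items <- c(items, it)
        ecs <- c(ecs, list(ecv))
        tax <- c(tax, if (nzchar(tv)) as.integer(tv) else NA_integer_)
        kos <- c(kos, list(kov[nzchar(kov)]))
    }
    if (anyDuplicated(items)) {
        # duplicate rows for one item merge their annotations (set union)
        keep <- !duplicated(items)
        for (it in unique(items[duplicated(items)])) {
            idx <- which(items == it)
            ecs[[idx[1]]] <- unique(unlist(ecs[idx]))
            kos[[idx[1]]] <- unique(unlist(kos[idx]))
            t <- tax[idx][!is.na(tax[idx])]
            tax[idx[1]] <- if (length(t)) t[1] else NA_integer_
        }
        items <- items[keep]; ecs <- ecs[keep]; kos <- kos[keep]; tax <- tax[keep]
    }
    new("FixtureResolver", batchSize = as.numeric(batchSize), mode = mode,
        items = items, ec = ecs, taxon = tax, ko = kos,
        equateIL = isTRUE(equateIL), calls = local({e <- new.env(); e$n <- 0L; e}))
}

#' @rdname resolveBatch
#' @export
setMethod("resolveBatch", "FixtureResolver", function(resolver, items) {
    if (length(items) > resolver@batchSize)
        stop(sprintf("batch of %d exceeds resolver batch size %d",
                     length(items), resolver@batchSize), call. = FALSE)
    resolver@calls$n <- resolver@calls$n + 1L
    key <- function(x) if (resolver@equateIL) chartr("I", "L", toupper(x)) else toupper(x)
    tabKeys <- key(resolver@items)
    hit <- match(key(items), tabKeys)
    out <- list()
    for (i in seq_along(items)) {
        j <- hit[i]
        if (is.na(j)) next
        out[[items[i]]] <- list(ec = resolver@ec[[j]],
                                taxonId = resolver@taxon[j],
                                ko = resolver@ko[[j]])
    }
    out
})

#' Annotate items with EC numbers, taxa and KO ids
#'
#' Deduplicates the items, chunks them into batches of at most the
#' resolver's batch size, dispatches each batch once, and merges the
#' results. Items the resolver does not know are simply absent from the
#' result (the count of unannotated items is attached as attribute
#' \code{"unannotated"}); that mirrors how an analysis proceeds when some
#' enzymes are not reported by the annotation service. Within one analysis
#' session each item is queried at most once: pass the same \code{cache}
#' environment across calls to memoize.
#'
#' @param items character vector of peptides or accessions (non-empty).
#' @param resolver an \linkS4class{AnnotationResolver}.
#' @param cache optional environment used as a memo keyed by
#'   \code{(mode, item)}; entries persist across calls that share it.
#' @return named list: item to record \code{list(ec, taxonId, ko)}.
#' @export
annotateItems <- function(items, resolver, cache = NULL) {
    stopifnot(length(items) >= 1L)
    items <- unique.default(items)
    memo <- !is.null(cache)
    ck <- function(x) paste0(resolver@mode, "\r", x)
    todo <- if (memo) items[!vapply(ck(items), exists, logical(1), envir = cache,
                                    inherits = FALSE)] else items
    results <- list()
    if (length(todo)) {
        nb <- ceiling(length(todo) / resolver@batchSize)
        for (b in seq_len(nb)) {
            lo <- (b - 1L) * resolver@batchSize + 1L
            hi <- min(b * resolver@batchSize, length(todo))
            got <- resolveBatch(resolver, todo[lo:hi])
            if (!is.list(got) || (length(got) && is.null(names(got))))
                stop("contract violation: resolver payload is not a named list",
                     call. = FALSE)
            results <- c(results, got)
        }
    }
    if (memo) {
        for (it in todo)
            assign(ck(it), results[[it]], envir = cache)
        results <- Filter(Negate(is.null),
                          stats::setNames(lapply(items, function(it)
                              get0(ck(it), envir = cache, inherits = FALSE)), items))
    }
    attr(results, "unannotated") <- length(items) - length(results)
    results
}
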