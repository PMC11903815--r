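#' Two-group differential abundance of peptides
#'
#' The peptide-mode contrast for one pathway node: \deqn{DA = Y/P_2 - X/P_1}
#' where X and Y are the matched peptide counts in groups 1 and 2 and P1,
#' P2 the groups' total peptide counts. Dividing by the totals prevents a
#' bias towards the bigger group, and bounds the value in [-1, 1]. The sign
#' convention follows the formula: positive means proportionally more
#' matches in the \emph{second} group.
#'
#' @param x,p1 matched count and total count of group 1 (0 <= x <= p1,
#'   p1 > 0). Vectorized.
#' @param y,p2 the same for group 2.
#' @return numeric in [-1, 1].
#' @examples
#' daPeptides(2, 10, 3, 10)   # 0.1
#' @export
daPeptides <- function(x, p1, y, p2) {
    if (any(p1 <= 0) || any(p2 <= 0))
        stop("undefined denominator: group totals must be > 0", call. = FALSE)
    if (any(x < 0) || any(y < 0) || any(x > p1) || any(y > p2))
        stop("counts must satisfy 0 <= x <= p1 and 0 <= y <= p2", call. = FALSE)
    y / p2 - x / p1
}

#' Two-group differential abundance of proteins (log2 fold-change)
#'
#' The protein-mode contrast: \deqn{DA = \log_2((Y/P_2)/(X/P_1))} with X, Y
#' the sums of matched protein abundances per group and P1, P2 the group
#' totals. A pseudocount is added to X and Y before the ratio; with the
#' default pseudocount of 0, zero numerators produce explicit sentinels
#' rather than silently clamped values: \code{+Inf} when only group 2 has
#' abundance, \code{-Inf} when only group 1 has, and \code{NaN} (undefined)
#' when neither does — so zero-abundance nodes saturate visually instead
#' of disappearing.
#'
#' @param x,y matched abundance sums of groups 1 and 2 (>= 0). Vectorized.
#' @param p1,p2 group total abundances (> 0).
#' @param pseudocount non-negative value added to x and y.
#' @return numeric; \code{+Inf}/\code{-Inf}/\code{NaN} sentinels possible.
#' @examples
#' daProteins(4, 2, 8, 2)     # log2((8/2)/(4/2)) = 1
#' @export
daProteins <- function(x, p1, y, p2, pseudocount = 0) {
    if (length(pseudocount) != 1L || is.na(pseudocount) || pseudocount < 0)
        stop("pseudocount must be a single non-negative number", call. = FALSE)
    if (any(p1 <= 0) || any(p2 <= 0))
        stop("undefined denominator: group totals must be > 0", call. = FALSE)
    if (any(x < 0) || any(y < 0))
        stop("abundance sums must be non-negative", call. = FALSE)
    xs <- x + pseudocount
    ys <- y + pseudocount
    out <- log2((ys / p2) / (xs / p1))
    out[xs == 0 & ys == 0] <- NaN
    out
}

#' Normalize values onto a diverging [-1, 1] scale
#'
#' Color ranges driven by raw minimum and maximum mislead when one side of
#' the midpoint dwarfs the other, so the two sides are normalized
#' independently — two sequential scales joined at a fixed midpoint.
#' Finite values above the midpoint are divided by the maximum positive
#' deviation (landing in (0, 1]); values below by the maximum negative
#' deviation (landing in [-1, 0)); the midpoint maps to 0. Infinite
#' sentinels map straight to ±1 and are excluded from scale estimation;
#' \code{NaN} (undefined) stays \code{NA}.
#'
#' @param values numeric vector, sentinels allowed.
#' @param midpoint the critical midpoint (0 for both DA modes).
#' @return numeric vector in [-1, 1] (with \code{NA} for undefined input).
#' @examples
#' normalizeDiverging(c(-0.2, 0, 0.8))   # -1 0 1
#' @export
normalizeDiverging <- function(values, midpoint = 0) {
    stopifnot(is.finite(midpoint))
    out <- rep(NA_real_, length(values))
    out[is.infinite(values) & values > 0] <- 1
    out[is.infinite(values) & values < 0] <- -1
    fin <- is.finite(values)
    d <- values[fin] - midpoint
    posMax <- if (any(d > 0)) max(d[d > 0]) else NA_real_
    negMax <- if (any(d < 0)) max(-d[d < 0]) else NA_real_
    scaled <- numeric(length(d))
    scaled[d > 0] <- d[d > 0] / posMax
    scaled[d < 0] <- d[d < 0] / negMax
    out[fin] <- scaled
    out
}

#' Per-node two-group comparison over one pathway
#'
#' Assembles, for every enzyme node of the selected pathway, the matched
#' weight (peptide mode) or matched abundance sum (protein mode) per group
#' — each item counted once per node — applies the mode's
#' differential-abundance formula against the group totals, and normalizes
#' the resulting values onto the diverging scale across this pathway's
#' node set (the set of values shown together in one view).
#'
#' @param index a \linkS4class{MappingIndex} built from exactly two groups.
#' @param mapId the selected pathway.
#' @param pseudocount protein mode only; see \code{\link{daProteins}}.
#' @return data.frame with one row per enzyme node: \code{nodeId},
#'   \code{label}, \code{x}, \code{p1}, \code{y}, \code{p2}, \code{daRaw},
#'   \code{daNorm}.
#' @export
comparePathway <- function(index, mapId, pseudocount = 0) {
    grp <- index@groupSet@groups
    if (nrow(grp) != 2L)
        stop("differential abundance needs exactly 2 groups; ",
             "the presence view remains available for single-group analyses",
             call. = FALSE)
    pw <- index@pathways[[mapId]]
    if (is.null(pw))
        stop(sprintf("unknown pathway '%s'", mapId), call. = FALSE)
    mode <- index@groupSet@mode
    abund <- mode == "protein"
    w1 <- itemGroupWeight(index@groupSet, grp$name[1], abundance = abund)
    w2 <- itemGroupWeight(index@groupSet, grp$name[2], abundance = abund)
    p1 <- grp$totalCount[1]; p2 <- grp$totalCount[2]
    nd <- pw@nodes
    enz <- nd[nd$kind == "enzyme", , drop = FALSE]
    h <- index@nodeHits[index@nodeHits$mapId == mapId, , drop = FALSE]
    x <- y <- numeric(nrow(enz))
    for (i in seq_len(nrow(enz))) {
        items <- unique(h$item[h$nodeId == enz$nodeId[i]])
        x[i] <- sum(w1[items[items %in% names(w1)]])
        y[i] <- sum(w2[items[items %in% names(w2)]])
    }
    daRaw <- if (mode == "peptide") daPeptides(x, p1, y, p2)
             else daProteins(x, p1, y, p2, pseudocount)
    data.frame(nodeId = enz$nodeId, label = enz$label,
               x = x, p1 = p1, y = y, p2 = p2,
               daRaw = daRaw, daNorm = normalizeDiverging(daRaw, 0),
               stringsAsFactors = FALSE)
}

#' Per-group presence flags for overlay segmentation
#'
#' The standard (presence) visualization highlights nodes with at least one
#' match; with several groups, each highlighted node is segmented into one
#' part per matched group. Returns, per matched node, a logical flag per
#' group; nodes matched by no group are omitted.
#'
#' @param index a \linkS4class{MappingIndex} (one or more groups).
#' @param mapId the selected pathway.
#' @return named list: node id (as character) to a named logical vector
#'   over groups.
#' @export
presenceSegments <- function(index, mapId) {
    grp <- index@groupSet@groups$name
    h <- index@nodeHits[index@nodeHits$mapId == mapId, , drop = FALSE]
    e <- index@groupSet@entries
    itemsByGroup <- lapply(grp, function(g) unique(e$item[e$group == g]))
    names(itemsByGroup) <- grp
    out <- list()
    for (n in unique(h$nodeId)) {
        items <- unique(h$item[h$nodeId == n])
        flags <- vapply(grp, function(g)
            any(items %in% itemsByGroup[[g]]), logical(1))
        if (any(flags)) out[[as.character(n)]] <- flags
    }
    out
}
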