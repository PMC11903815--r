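#' Render a pathway overlay as SVG
#'
#' Builds a standalone SVG 1.1 overlay of one pathway on a white canvas
#' sized to the pathway's geometry bounding box. Node boxes use KGML
#' geometry (centre coordinates converted to top-left corners; pixel
#' units, y downward).
#'
#' Two views exist. The \emph{presence} view takes the output of
#' \code{\link{presenceSegments}} and splits each highlighted node box
#' into equal vertical segments, one per matched group, each with that
#' group's color. The \emph{differential-abundance} view takes the output
#' of \code{\link{comparePathway}} and fills each enzyme node with a
#' diverging colormap (blue-white-red, midpoint white) evaluated at its
#' normalized value, and adds a linear legend bar in place of a categorical
#' legend. Nodes without geometry are skipped with a warning.
#'
#' @param pathway a \linkS4class{PathwayGraph}.
#' @param comparison a \code{\link{comparePathway}} data.frame (DA view);
#'   exactly one of \code{comparison}/\code{segments} must be given.
#' @param segments a \code{\link{presenceSegments}} list (presence view).
#' @param groupColors colors used for presence segments, recycled over
#'   groups.
#' @param colorStops diverging colormap stops, low/mid/high.
#' @return SVG content as a single string.
#' @export
renderOverlay <- function(pathway, comparison = NULL, segments = NULL,
                          groupColors = c("#1B9E77", "#D95F02", "#7570B3"),
                          colorStops = c("#2166AC", "#FFFFFF", "#B2182B")) {
    stopifnot(xor(is.null(comparison), is.null(segments)))
    nd <- pathway@nodes
    geom <- nd[!is.na(nd$x), , drop = FALSE]
    pad <- 20
    wCanvas <- max(geom$x + geom$width / 2, 0) + pad
    hCanvas <- max(geom$y + geom$height / 2, 0) + pad + 40  # room for legend
    rects <- character(0)
    num <- function(v) sprintf("%.10g", v)
    addRect <- function(x, y, w, h, fill, stroke = "#333333", opacity = 0.85) {
        rects <<- c(rects, sprintf(
            '<rect x="%s" y="%s" width="%s" height="%s" fill="%s" stroke="%s" fill-opacity="%s"/>',
            num(x), num(y), num(w), num(h), fill, stroke, num(opacity)))
    }
    lookup <- function(id) {
        i <- match(id, nd$nodeId)
        if (is.na(i) || is.na(nd$x[i])) {
            warning(sprintf("node %s has no geometry; skipped", id), call. = FALSE)
            return(NULL)
        }
        nd[i, , drop = FALSE]
    }
    legend <- character(0)
    if (!is.null(segments)) {
        groups <- names(segments[[1]])
        cols <- rep(groupColors, length.out = length(groups))
        for (id in names(segments)) {
            n <- lookup(as.integer(id))
            if (is.null(n)) next
            flags <- segments[[id]]
            on <- which(flags)
            k <- length(on)
            segW <- n$width / k
            for (j in seq_len(k))
                addRect(n$x - n$width / 2 + (j - 1) * segW, n$y - n$height / 2,
                        segW, n$height, cols[on[j]])
        }
        legend <- sprintf(
            '<text x="%s" y="%s" font-size="11">%s</text>',
            num(pad), num(hCanvas - 15),
            paste(sprintf("%s: %s", groups, cols[seq_along(groups)]),
                  collapse = "   "))
    } else {
        ramp <- grDevices::colorRamp(colorStops)
        fillFor <- function(v) {
            if (is.na(v)) return("#BBBBBB")   # undefined sentinel: neutral grey
            rgb <- ramp((v + 1) / 2)
            grDevices::rgb(rgb[1], rgb[2], rgb[3], maxColorValue = 255)
        }
        # highlight = matched at least once in either group
        shown <- comparison[comparison$x > 0 | comparison$y > 0, , drop = FALSE]
        for (i in seq_len(nrow(shown))) {
            n <- lookup(shown$nodeId[i])
            if (is.null(n)) next
            addRect(n$x - n$width / 2, n$y - n$height / 2, n$width, n$height,
                    fillFor(shown$daNorm[i]))
        }
        # linear legend: one gradient-filled bar with min/mid/max ticks
        legend <- c(
            '<defs><linearGradient id="dascale" x1="0" y1="0" x2="1" y2="0">',
            sprintf('<stop offset="0%%" stop-color="%s"/>', colorStops[1]),
            sprintf('<stop offset="50%%" stop-color="%s"/>', colorStops[2]),
            sprintf('<stop offset="100%%" stop-color="%s"/>', colorStops[3]),
            '</linearGradient></defs>',
            sprintf('<rect x="%s" y="%s" width="120" height="12" fill="url(#dascale)" stroke="#333333" class="legend"/>',
                    num(pad), num(hCanvas - 32)),
            sprintf('<text x="%s" y="%s" font-size="10">-1</text>',
                    num(pad), num(hCanvas - 6)),
            sprintf('<text x="%s" y="%s" font-size="10">0</text>',
                    num(pad + 56), num(hCanvas - 6)),
            sprintf('<text x="%s" y="%s" font-size="10">1</text>',
                    num(pad + 114), num(hCanvas - 6)))
    }
    paste0(
        '<?xml version="1.0" encoding="UTF-8"?>\n',
        sprintf('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%s" height="%s" viewBox="0 0 %s %s" style="background:#FFFFFF">\n',
                num(wCanvas), num(hCanvas), num(wCanvas), num(hCanvas)),
        sprintf('<title>%s (%s)</title>\n', pathway@name, pathway@mapId),
        paste(rects, collapse = "\n"), "\n",
        paste(legend, collapse = "\n"), "\n</svg>\n")
}
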