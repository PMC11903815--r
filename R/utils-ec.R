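#' Enzyme Commission number helpers
#'
#' EC numbers are four dot-separated fields (class, subclass, sub-subclass,
#' serial), e.g. \code{"2.3.1.9"}. A trailing \code{"-"} denotes an
#' unspecified sub-class; once a field is \code{"-"} every later field must
#' be \code{"-"} too (so \code{"2.8.3.-"} and \code{"2.8.-.-"} are legal,
#' \code{"2.-.3.9"} is not). The first field is always numeric.
#'
#' @param ec character vector of candidate EC strings.
#' @return \code{isValidEC} returns a logical vector.
#' @examples
#' isValidEC(c("2.3.1.9", "2.8.3.-", "2.-.3.9"))
#' @export
isValidEC <- function(ec) {
    if (length(ec) == 0L) return(logical(0))
    vapply(ec, function(e) {
        if (is.na(e) || !nzchar(e)) return(FALSE)
        f <- strsplit(e, ".", fixed = TRUE)[[1]]
        if (length(f) != 4L) return(FALSE)
        isnum <- grepl("^[0-9]+$", f)
        dash <- f == "-"
        if (!all(isnum | dash)) return(FALSE)
        if (!isnum[1]) return(FALSE)
        # dashes only as a trailing run
        if (any(dash) && any(isnum[seq_along(f) > which(dash)[1]])) return(FALSE)
        TRUE
    }, logical(1), USE.NAMES = FALSE)
}

#' @describeIn isValidEC does EC \code{a} match EC \code{b}? A trailing
#'   \code{"-"} in either operand matches any value in that and all later
#'   positions, so \code{"2.8.3.-"} matches \code{"2.8.3.8"} and vice versa.
#' @param a,b single EC strings (wildcards allowed).
#' @export
ecMatches <- function(a, b) {
    fa <- strsplit(a, ".", fixed = TRUE)[[1]]
    fb <- strsplit(b, ".", fixed = TRUE)[[1]]
    for (i in 1:4) {
        if (fa[i] == "-" || fb[i] == "-") return(TRUE)
        if (fa[i] != fb[i]) return(FALSE)
    }
    TRUE
}

# vectorized over `targets`
ecMatchesAny <- function(query, targets) {
    if (length(targets) == 0L) return(FALSE)
    any(vapply(targets, function(t) ecMatches(query, t), logical(1)))
}

stopIfBadEC <- function(ec, rows = NULL, what = "EC") {
    bad <- !isValidEC(ec)
    if (any(bad)) {
        i <- which(bad)[1]
        loc <- if (!is.null(rows)) sprintf(" (row %d)", rows[i]) else ""
        stop(sprintf("malformed %s string '%s'%s", what, ec[i], loc), call. = FALSE)
    }
    invisible(TRUE)
}
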