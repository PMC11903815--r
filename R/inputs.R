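#' Parse a peptide-list sample file
#'
#' One peptide sequence per line, UTF-8 plain text. Parsing is total: every
#' non-blank line yields either one peptide entry or one line error, blank
#' lines are skipped silently, and parsing never aborts early — all
#' malformed lines are reported together with their 1-based line number and
#' a reason, so a formatting error on the last line is caught before any
#' upload work starts. Repeated sequences are merged with their occurrence
#' count (multiplicity) incremented; multiplicities are what enter the
#' group denominators and match counts downstream (pass the entries through
#' \code{unique = TRUE} in \code{\link{assembleGroups}} callers to collapse
#' them instead).
#'
#' Sequences are validated against the 20 canonical amino-acid letters;
#' \code{extraResidues} extends the alphabet (e.g. \code{c("U", "X")}).
#' I and L are both legal and kept distinct at parse time — collapsing the
#' two isobaric residues is the annotation layer's concern.
#'
#' @param text raw file content (single string) or a character vector of
#'   lines.
#' @param sampleId non-empty sample identifier.
#' @param extraResidues extra legal residue letters beyond the canonical 20.
#' @return list with \code{entries} (data.frame: \code{sequence},
#'   \code{sampleId}, \code{multiplicity}) and \code{errors} (data.frame:
#'   \code{lineNumber}, \code{rawLine}, \code{reason}).
#' @examples
#' parsePeptides("AAK\nMLK\nAAK\n", "s1")$entries
#' @export
parsePeptides <- function(text, sampleId, extraResidues = character(0)) {
    stopifnot(is.character(sampleId), length(sampleId) == 1L, nzchar(sampleId))
    lines <- splitLines(text)
    alphabet <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], extraResidues)
    seqs <- toupper(trimws(lines))
    blank <- !nzchar(seqs)
    badChar <- vapply(seqs, function(s) {
        if (!nzchar(s)) return("")
        ch <- strsplit(s, "")[[1]]
        bad <- setdiff(unique(ch), alphabet)
        if (length(bad)) bad[1] else ""
    }, character(1), USE.NAMES = FALSE)
    isErr <- !blank & nzchar(badChar)
    errors <- data.frame(
        lineNumber = which(isErr),
        rawLine = lines[isErr],
        reason = sprintf("invalid character '%s' in peptide sequence", badChar[isErr]),
        stringsAsFactors = FALSE
    )
    ok <- seqs[!blank & !isErr]
    if (length(ok)) {
        tab <- table(ok)
        entries <- data.frame(
            sequence = names(tab),
            sampleId = sampleId,
            multiplicity = as.integer(tab),
            stringsAsFactors = FALSE
        )
        entries <- entries[orderC(entries$sequence), , drop = FALSE]
        rownames(entries) <- NULL
    } else {
        entries <- data.frame(sequence = character(0), sampleId = character(0),
                              multiplicity = integer(0), stringsAsFactors = FALSE)
    }
    list(entries = entries, errors = errors)
}

#' Parse a protein-table sample file
#'
#' Two columns — UniProtKB-style accession and a numeric abundance (area,
#' spectral or absolute count) — separated by a tab or comma
#' (auto-detected per line). A single optional header line is auto-detected
#' and skipped: a first line whose second field is non-numeric is taken as
#' a header, which tolerates common exports without a dialect flag. Lines
#' with a missing field, a malformed accession, or a missing/non-numeric/
#' negative abundance yield line errors; as with peptides, parsing is total
#' and all problems are reported.
#'
#' The accession grammar accepted is 6 or 10 alphanumeric characters with a
#' leading letter (the UniProtKB accession shape).
#'
#' @inheritParams parsePeptides
#' @return list with \code{entries} (data.frame: \code{accession},
#'   \code{abundance}, \code{sampleId}) and \code{errors} as in
#'   \code{\link{parsePeptides}}.
#' @examples
#' parseProteins("accession\tabundance\nP12345\t2\n", "s1")$entries
#' @export
parseProteins <- function(text, sampleId) {
    stopifnot(is.character(sampleId), length(sampleId) == 1L, nzchar(sampleId))
    lines <- splitLines(text)
    n <- length(lines)
    acc <- character(0); ab <- numeric(0)
    errLine <- integer(0); errRaw <- character(0); errWhy <- character(0)
    accRe <- "^[A-Za-z][A-Za-z0-9]{5}([A-Za-z0-9]{4})?$"
    headerSkipped <- FALSE
    for (i in seq_len(n)) {
        raw <- lines[i]
        line <- trimws(raw)
        if (!nzchar(line)) next
        sep <- if (grepl("\t", line)) "\t" else ","
        f <- trimws(strsplit(line, sep, fixed = TRUE)[[1]])
        f <- f[nzchar(f) | seq_along(f) <= 2]
        val <- suppressWarnings(as.numeric(f[2]))
        # header: first line whose second field is non-numeric and whose
        # first field is not itself accession-shaped (so a data line with a
        # bad abundance is still reported as an error, not eaten)
        if (i == 1L && length(f) >= 2 && is.na(val) && !grepl(accRe, f[1])) {
            headerSkipped <- TRUE
            next
        }
        if (length(f) < 2L || !nzchar(f[2] %||% "")) {
            errLine <- c(errLine, i); errRaw <- c(errRaw, raw)
            errWhy <- c(errWhy, "missing abundance field")
        } else if (is.na(val)) {
            errLine <- c(errLine, i); errRaw <- c(errRaw, raw)
            errWhy <- c(errWhy, sprintf("non-numeric abundance '%s'", f[2]))
        } else if (val < 0) {
            errLine <- c(errLine, i); errRaw <- c(errRaw, raw)
            errWhy <- c(errWhy, "negative abundance")
        } else if (!grepl(accRe, f[1])) {
            errLine <- c(errLine, i); errRaw <- c(errRaw, raw)
            errWhy <- c(errWhy, sprintf("malformed accession '%s'", f[1]))
        } else {
            acc <- c(acc, toupper(f[1])); ab <- c(ab, val)
        }
    }
    entries <- data.frame(accession = acc, abundance = ab,
                          sampleId = rep(sampleId, length(acc)),
                          stringsAsFactors = FALSE)
    attr(entries, "headerSkipped") <- headerSkipped
    list(entries = entries,
         errors = data.frame(lineNumber = errLine, rawLine = errRaw,
                             reason = errWhy, stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

splitLines <- function(text) {
    if (length(text) == 1L && grepl("[\r\n]", text))
        strsplit(gsub("\r\n?", "\n", text), "\n", fixed = TRUE)[[1]]
    else as.character(text)
}

#' Assemble parsed samples into comparison groups
#'
#' Groups one or two named sets of samples and computes each group's total
#' count — the P1/P2 denominators of the differential-abundance formulas:
#' summed peptide multiplicities in peptide mode, summed protein abundances
#' in protein mode. Group order is preserved as given; the first group is
#' "group 1" of the formulas. Exactly one or two groups are supported
#' (two-group comparison); richer designs are rejected.
#'
#' @param samples named list: sample id to the \code{entries} data.frame
#'   from \code{\link{parsePeptides}} or \code{\link{parseProteins}}.
#' @param assignment named character vector: sample id to group name. Every
#'   sample must be assigned to exactly one group.
#' @param mode \code{"peptide"} or \code{"protein"}.
#' @param unique collapse repeated peptide sequences to multiplicity 1
#'   before totalling (peptide mode only).
#' @return a \linkS4class{SampleGroupSet}.
#' @examples
#' s1 <- parsePeptides("AAK\nAAK\nMLK\n", "s1")$entries
#' s2 <- parsePeptides("CCK\nMLK\nAAK\nTTK\n", "s2")$entries
#' groupTable(assembleGroups(list(s1 = s1, s2 = s2),
#'                           c(s1 = "ctrl", s2 = "ctrl"), "peptide"))
#' @export
assembleGroups <- function(samples, assignment, mode = c("peptide", "protein"),
                           unique = FALSE) {
    mode <- match.arg(mode)
    stopifnot(is.list(samples), length(samples) >= 1L)
    missing <- setdiff(names(samples), names(assignment))
    if (length(missing))
        stop(sprintf("sample '%s' is not assigned to any group", missing[1]),
             call. = FALSE)
    groups <- unique.default(unname(assignment[names(samples)]))
    if (length(groups) > 2L)
        stop(sprintf("unsupported design: %d groups given, at most 2 supported",
                     length(groups)), call. = FALSE)
    rows <- lapply(names(samples), function(sid) {
        e <- samples[[sid]]
        if (nrow(e) == 0L)
            return(data.frame(item = character(0), sampleId = character(0),
                              group = character(0), weight = numeric(0),
                              abundance = numeric(0), stringsAsFactors = FALSE))
        if (mode == "peptide") {
            w <- if (unique) rep(1L, nrow(e)) else e$multiplicity
            data.frame(item = e$sequence, sampleId = sid,
                       group = unname(assignment[sid]), weight = as.numeric(w),
                       abundance = NA_real_, stringsAsFactors = FALSE)
        } else {
            data.frame(item = e$accession, sampleId = sid,
                       group = unname(assignment[sid]), weight = 1,
                       abundance = e$abundance, stringsAsFactors = FALSE)
        }
    })
    entries <- do.call(rbind, rows)
    totals <- vapply(groups, function(g) {
        e <- entries[entries$group == g, , drop = FALSE]
        if (mode == "peptide") sum(e$weight) else sum(e$abundance)
    }, numeric(1))
    new("SampleGroupSet", mode = mode, entries = entries,
        groups = data.frame(name = groups, totalCount = unname(totals),
                            stringsAsFactors = FALSE))
}
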