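#' Validate input files without running an analysis
#'
#' Runs the mode's parser over each file and collects every malformed line
#' with its file, 1-based line number and reason. Status 0 means all files
#' clean, 1 means at least one line error, 2 means at least one file could
#' not be read.
#'
#' @param files character vector of file paths.
#' @param mode \code{"peptide"} or \code{"protein"}.
#' @return list with \code{status} and \code{report} (data.frame:
#'   \code{file}, \code{lineNumber}, \code{rawLine}, \code{reason}).
#' @export
validateInputFiles <- function(files, mode = c("peptide", "protein")) {
    mode <- match.arg(mode)
    report <- data.frame(file = character(0), lineNumber = integer(0),
                         rawLine = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
    status <- 0L
    for (f in files) {
        if (!file.exists(f)) {
            status <- 2L
            report <- rbind(report, data.frame(
                file = f, lineNumber = NA_integer_, rawLine = "",
                reason = "file not readable", stringsAsFactors = FALSE))
            next
        }
        text <- readLines(f, warn = FALSE)
        parsed <- if (mode == "peptide") parsePeptides(text, basename(f))
                  else parseProteins(text, basename(f))
        if (nrow(parsed$errors)) {
            if (status == 0L) status <- 1L
            report <- rbind(report, cbind(file = f, parsed$errors))
        }
    }
    list(status = status, report = report)
}

#' Run the full mapping/comparison pipeline from a config
#'
#' Declarative one-shot driver: parse and group the sample files, annotate
#' through the configured resolver, build the mapping index against the
#' configured pathway collection, and write the dense mapping CSV, the
#' ordered pathway list CSV, and — per selected pathway — the per-node
#' comparison CSV and SVG overlay, plus a machine-readable JSON run
#' manifest recording the config hash and seed. Outputs are deterministic
#' given fixed inputs: re-running the same config yields byte-identical
#' CSVs.
#'
#' Config fields (a YAML/JSON file or an R list):
#' \describe{
#'   \item{mode}{"peptide" or "protein".}
#'   \item{samples}{list of \code{\{file, sample_id?, group\}}.}
#'   \item{resolver}{\code{\{table: <TSV path>, batch_size?, equate_il?\}}.}
#'   \item{pathways}{directory containing \code{*.xml} KGML files (and
#'     optionally \code{ec2map.tsv}, \code{ec2rn.tsv}, \code{ec2cpd.tsv}),
#'     or a list of XML file paths.}
#'   \item{select}{map ids to render, or \code{top_n} for the best-ranked.}
#'   \item{out}{output directory.}
#'   \item{seed}{integer; recorded in the manifest.}
#'   \item{unique}{collapse repeated peptides (default FALSE).}
#'   \item{pseudocount}{protein mode (default 0).}
#' }
#'
#' @param config path to a YAML/JSON config file, or an equivalent list.
#' @param out optional output directory overriding the config's.
#' @return invisibly, a list with the \linkS4class{MappingIndex}, the
#'   ranking, the comparisons and the output paths.
#' @export
runAnalysis <- function(config, out = NULL) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    cfgErr <- function(path, why)
        stop(sprintf("config schema violation at %s: %s", path, why),
             call. = FALSE)
    mode <- config$mode %||% cfgErr("mode", "missing")
    if (!mode %in% c("peptide", "protein")) cfgErr("mode", "must be peptide|protein")
    if (is.null(config$samples) || !length(config$samples))
        cfgErr("samples", "missing or empty")
    outDir <- out %||% config$out %||% cfgErr("out", "missing")
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

    samples <- list(); assignment <- character(0); reports <- list()
    for (i in seq_along(config$samples)) {
        s <- config$samples[[i]]
        if (is.null(s$file) || is.null(s$group))
            cfgErr(sprintf("samples[%d]", i), "needs file and group")
        sid <- s$sample_id %||% basename(s$file)
        text <- readLines(s$file, warn = FALSE)
        parsed <- if (mode == "peptide") parsePeptides(text, sid)
                  else parseProteins(text, sid)
        if (nrow(parsed$errors))
            warning(sprintf("%d malformed line(s) in %s", nrow(parsed$errors),
                            s$file), call. = FALSE)
        samples[[sid]] <- parsed$entries
        assignment[sid] <- s$group
    }
    groupSet <- assembleGroups(samples, assignment, mode,
                               unique = isTRUE(config$unique))

    if (is.null(config$resolver$table)) cfgErr("resolver.table", "missing")
    resolver <- loadFixtureResolver(
        config$resolver$table, mode = mode,
        batchSize = config$resolver$batch_size %||% 1000,
        equateIL = isTRUE(config$resolver$equate_il))
    ann <- annotateItems(unique(groupSet@entries$item), resolver)

    pw <- config$pathways %||% cfgErr("pathways", "missing")
    if (length(pw) == 1L && dir.exists(pw)) {
        xmls <- sort(list.files(pw, pattern = "\\.xml$", full.names = TRUE))
        lt <- loadLinkTables(
            ecToMaps = optFile(file.path(pw, "ec2map.tsv")),
            ecToReactions = optFile(file.path(pw, "ec2rn.tsv")),
            ecToCompounds = optFile(file.path(pw, "ec2cpd.tsv")))
    } else {
        xmls <- unlist(pw)
        lt <- loadLinkTables()
    }
    if (!length(xmls)) cfgErr("pathways", "no KGML files found")
    pathways <- lapply(xmls, parseKGML)
    index <- buildMappingIndex(groupSet, ann, pathways, lt)
    ranked <- rankPathways(index)

    sel <- config$select
    mapIds <- if (is.null(sel)) ranked$mapId[ranked$count > 0]
        else if (is.list(sel) && !is.null(sel$top_n))
            utils::head(ranked$mapId, sel$top_n)
        else unlist(sel)
    unknown <- setdiff(mapIds, ranked$mapId)
    if (length(unknown))
        stop(sprintf("unknown pathway selected: %s",
                     paste(unknown, collapse = ", ")), call. = FALSE)

    paths <- list(dense = file.path(outDir, "dense_mapping.csv"),
                  pathwayList = file.path(outDir, "pathway_list.csv"))
    exportDense(index, paths$dense)
    exportPathwayList(ranked, paths$pathwayList)
    comparisons <- list()
    twoGroups <- nrow(groupSet@groups) == 2L
    for (m in mapIds) {
        if (twoGroups) {
            cmp <- comparePathway(index, m,
                                  pseudocount = config$pseudocount %||% 0)
            comparisons[[m]] <- cmp
            exportNodeComparison(cmp, file.path(outDir,
                                 sprintf("node_comparison_%s.csv", m)))
            svg <- renderOverlay(index@pathways[[m]], comparison = cmp)
        } else {
            svg <- renderOverlay(index@pathways[[m]],
                                 segments = presenceSegments(index, m))
        }
        writeText(svg, file.path(outDir, sprintf("overlay_%s.svg", m)))
    }
    manifest <- list(
        config_hash = hashConfig(config),
        seed = config$seed %||% NA,
        mode = mode,
        n_samples = length(samples),
        groups = groupSet@groups,
        selected = as.list(mapIds),
        unannotated_items = attr(ann, "unannotated"))
    jsonlite::write_json(manifest, file.path(outDir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, dataframe = "rows")
    invisible(list(index = index, ranked = ranked, comparisons = comparisons,
                   paths = paths, outDir = outDir))
}

optFile <- function(p) if (file.exists(p)) p else NULL

hashConfig <- function(config) {
    tmp <- tempfile()
    on.exit(unlink(tmp))
    writeText(jsonlite::toJSON(config, auto_unbox = TRUE), tmp)
    unname(tools::md5sum(tmp))
}

#' Case-study concordance against the packaged enzyme reference set
#'
#' Re-runs the two-group comparison workflow against the 32-enzyme
#' reference table: for each reference enzyme, whether the resolver
#' reported any matching item, the differential abundance of its EC
#' (computed item-wise under the peptide formula), a three-way sign
#' category (up/down/unaltered, with \code{|DA| <= epsilon} counting as
#' unaltered), and its exclusion status (an EC with no associated pathway
#' map is excluded from the comparison). The summary counts enzymes whose
#' observed direction agrees with the reference table's expected label.
#'
#' @param index a \linkS4class{MappingIndex} built from two groups (group 1
#'   is the reference condition, group 2 the treatment).
#' @param reference a \code{\link{table1Fixture}}-shaped data.frame.
#' @param epsilon zero-tolerance for the "unaltered" category (default 0:
#'   the three-way categorization has no stated threshold).
#' @return list with \code{perEnzyme} (data.frame) and \code{summary}
#'   (list: \code{compared}, \code{concordant}, \code{discordant},
#'   \code{notReported}, \code{excluded}).
#' @export
runCaseStudy <- function(index, reference = table1Fixture(), epsilon = 0) {
    grp <- index@groupSet@groups
    if (nrow(grp) != 2L)
        stop("case study needs exactly 2 groups", call. = FALSE)
    w1 <- itemGroupWeight(index@groupSet, grp$name[1])
    w2 <- itemGroupWeight(index@groupSet, grp$name[2])
    p1 <- grp$totalCount[1]; p2 <- grp$totalCount[2]
    items <- names(index@itemToEcs)
    n <- nrow(reference)
    matched <- logical(n); da <- rep(NA_real_, n)
    category <- character(n)
    for (i in seq_len(n)) {
        ecs <- trimws(strsplit(reference$ec[i], ";", fixed = TRUE)[[1]])
        # exact EC equality, not wildcard matching: the reference table keeps
        # 2.8.3.-, 2.8.3.1, 2.8.3.8 and 2.8.3.12 as distinct enzymes, so a
        # peptide annotated with one member of the family must not feed the
        # other rows (a partial EC matches only an identical partial one)
        hit <- items[vapply(items, function(it)
            any(ecs %in% index@itemToEcs[[it]]), logical(1))]
        matched[i] <- length(hit) > 0
        noPathway <- is.na(reference$mapId[i])
        if (!matched[i]) {
            category[i] <- "not reported"
        } else if (noPathway) {
            category[i] <- "excluded"
        } else {
            x <- sum(w1[hit[hit %in% names(w1)]])
            y <- sum(w2[hit[hit %in% names(w2)]])
            da[i] <- daPeptides(x, p1, y, p2)
            category[i] <- if (abs(da[i]) <= epsilon) "unaltered"
                           else if (da[i] > 0) "up" else "down"
        }
    }
    per <- data.frame(enzyme = reference$enzyme, ec = reference$ec,
                      mapId = reference$mapId, section = reference$section,
                      matched = matched, daRaw = da, category = category,
                      expected = reference$expectedDirection,
                      stringsAsFactors = FALSE)
    comparedIdx <- !category %in% c("not reported", "excluded")
    per$concordant <- ifelse(comparedIdx, per$category == per$expected, NA)
    list(perEnzyme = per,
         summary = list(
             compared = sum(comparedIdx),
             concordant = sum(per$concordant, na.rm = TRUE),
             discordant = sum(!per$concordant, na.rm = TRUE),
             notReported = sum(category == "not reported"),
             excluded = sum(category == "excluded")))
}
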