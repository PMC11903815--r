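#' Generate a synthetic pathway graph
#'
#' Emits a connected alternating compound-enzyme chain as KGML-dialect XML
#' plus the matching EC link-table rows, with synthetic EC numbers (class
#' 9, a class unused by real enzymes, so synthetic annotations can never
#' collide with genuine ones) and box geometry on a regular grid. Every
#' enzyme catalyses one reaction between its flanking compounds.
#' Deterministic for a given seed: the same call yields identical bytes.
#'
#' @param nEnzymes,nCompounds chain composition (both >= 1).
#' @param seed integer seed.
#' @param mapNumber 5-digit number for the synthetic map id.
#' @return list with \code{kgml} (XML string), \code{ecs} (the enzyme ECs
#'   in chain order), \code{linkMaps}, \code{linkReactions},
#'   \code{linkCompounds} (two-column TSV strings for
#'   \code{\link{loadLinkTables}}).
#' @export
generatePathway <- function(nEnzymes, nCompounds, seed, mapNumber = 99001) {
    stopifnot(nEnzymes >= 1, nCompounds >= 1)
    set.seed(seed)
    mapid <- sprintf("map%05d", mapNumber)
    ecs <- sprintf("9.%d.%d.%d", sample(1:9, nEnzymes, replace = TRUE),
                   sample(1:99, nEnzymes, replace = TRUE), seq_len(nEnzymes))
    cpds <- sprintf("C9%04d", seq_len(nCompounds))
    # alternating chain starting with a compound; leftovers of the longer
    # kind run consecutively at the tail so the graph stays connected
    kinds <- character(0); ei <- ci <- 0L
    for (k in seq_len(nEnzymes + nCompounds)) {
        takeC <- (k %% 2L == 1L && ci < nCompounds) || ei >= nEnzymes
        if (takeC) { ci <- ci + 1L; kinds <- c(kinds, "compound") }
        else       { ei <- ei + 1L; kinds <- c(kinds, "enzyme") }
    }
    n <- length(kinds)
    ids <- seq_len(n)
    entry <- character(0)
    eSeen <- cSeen <- 0L
    ecOf <- integer(n); cpdOf <- integer(n)
    for (k in ids) {
        xx <- 60 + 90 * ((k - 1) %% 8)
        yy <- 80 + 60 * ((k - 1) %/% 8)
        if (kinds[k] == "enzyme") {
            eSeen <- eSeen + 1L; ecOf[k] <- eSeen
            entry <- c(entry, sprintf(
                '  <entry id="%d" name="ec:%s" type="enzyme" reaction="rn:R9%04d">\n    <graphics name="%s" x="%d" y="%d" width="46" height="17"/>\n  </entry>',
                k, ecs[eSeen], eSeen, ecs[eSeen], xx, yy))
        } else {
            cSeen <- cSeen + 1L; cpdOf[k] <- cSeen
            entry <- c(entry, sprintf(
                '  <entry id="%d" name="cpd:%s" type="compound">\n    <graphics name="%s" x="%d" y="%d" width="8" height="8"/>\n  </entry>',
                k, cpds[cSeen], cpds[cSeen], xx, yy))
        }
    }
    # one reaction per enzyme: substrate = nearest compound before it in the
    # chain, product = nearest after (falling back to the other side)
    reactions <- character(0)
    linkR <- character(0); linkC <- character(0)
    cpdPos <- which(kinds == "compound")
    for (k in which(kinds == "enzyme")) {
        before <- cpdPos[cpdPos < k]; after <- cpdPos[cpdPos > k]
        s <- if (length(before)) max(before) else min(after)
        p <- if (length(after)) min(after) else max(before)
        reactions <- c(reactions, sprintf(
            '  <reaction id="%d" type="reversible">\n    <substrate id="%d"/>\n    <product id="%d"/>\n  </reaction>',
            k, s, p))
        e <- ecs[ecOf[k]]
        linkR <- c(linkR, sprintf("%s\tR9%04d", e, ecOf[k]))
        linkC <- c(linkC, sprintf("%s\t%s", e, cpds[cpdOf[s]]),
                   sprintf("%s\t%s", e, cpds[cpdOf[p]]))
    }
    kgml <- paste0(
        '<?xml version="1.0"?>\n',
        sprintf('<pathway name="path:%s" title="Synthetic chain pathway %d" category="Synthetic">\n',
                mapid, mapNumber),
        paste(entry, collapse = "\n"), "\n",
        paste(reactions, collapse = "\n"), "\n</pathway>\n")
    list(kgml = kgml, ecs = ecs,
         linkMaps = paste(sprintf("%s\t%s", ecs, mapid), collapse = "\n"),
         linkReactions = paste(linkR, collapse = "\n"),
         linkCompounds = paste(unique(linkC), collapse = "\n"))
}

#' Generate a small synthetic taxonomy
#'
#' A three-level tree — root (id 1), \code{nGenera} genus nodes, and
#' \code{nSpecies} species leaves attached round-robin to the genera — as
#' the flat TSV format \code{\link{loadTaxonomy}} consumes.
#'
#' @param nGenera,nSpecies tree composition.
#' @return TSV content (single string).
#' @export
generateTaxonomy <- function(nGenera = 3, nSpecies = 6) {
    rows <- c("taxon_id\tparent_id\trank\tname",
              "1\t1\tno rank\troot")
    for (g in seq_len(nGenera))
        rows <- c(rows, sprintf("%d\t1\tgenus\tGenus_%d", 10 + g, g))
    for (s in seq_len(nSpecies))
        rows <- c(rows, sprintf("%d\t%d\tspecies\tSpecies_%d",
                                100 + s, 10 + ((s - 1) %% nGenera) + 1, s))
    paste0(paste(rows, collapse = "\n"), "\n")
}

#' A planted enrichment effect
#'
#' Describes one EC whose group-2 draw rate is multiplied by
#' \code{enrichmentFactor} (then renormalized with the rest of the pool).
#' Under the peptide formula's sign convention, a factor above 1 implies an
#' expected positive differential abundance for nodes carrying that EC.
#'
#' @param targetEc EC string.
#' @param enrichmentFactor positive group-2 rate multiplier.
#' @param baselineRate per-item draw probability in group 1.
#' @return list of class \code{"PlantedEffect"}.
#' @export
plantedEffect <- function(targetEc, enrichmentFactor, baselineRate) {
    stopifnot(isValidEC(targetEc), enrichmentFactor > 0,
              baselineRate > 0, baselineRate <= 1)
    structure(list(targetEc = targetEc, enrichmentFactor = enrichmentFactor,
                   baselineRate = baselineRate,
                   expectedSign = sign(enrichmentFactor - 1)),
              class = "PlantedEffect")
}

#' Generate two-group peptide samples with planted enrichment
#'
#' Draws peptides i.i.d. from an EC-labelled pool. Each EC label owns a
#' pool of unique random 8-12-mers over the canonical alphabet (pools are
#' disjoint, so no accidental cross-annotation); the remaining probability
#' mass produces unannotated background peptides. In group 2, each planted
#' effect's target rate is multiplied by its enrichment factor and the
#' whole probability vector renormalized. Everything the pipeline consumes
#' is emitted consistently: one peptide-list file per sample, an
#' annotation TSV covering all labelled pools (each peptide also carries a
#' taxon drawn from the supplied taxonomy's species), and a truth record
#' with each effect's expected differential-abundance sign.
#'
#' @param nPerSample peptide draws per sample.
#' @param effects list of \code{\link{plantedEffect}}s (possibly empty).
#' @param seed integer seed; all randomness flows from it.
#' @param ecs EC labels of the pool; defaults to the effect targets plus
#'   fillers to reach at least 4 labels.
#' @param nSamplesPerGroup samples per group.
#' @param baselineRate draw rate of each non-target EC label.
#' @param poolSize unique peptides per EC label.
#' @param taxa integer vector of taxon ids to label pools with (recycled).
#' @return list with \code{sampleText} (named list of file contents),
#'   \code{assignment} (sample to group), \code{annotationTsv},
#'   \code{truth} (data.frame \code{ec}, \code{factor},
#'   \code{expectedSign}).
#' @export
generateSamples <- function(nPerSample, effects = list(), seed,
                            ecs = NULL, nSamplesPerGroup = 1,
                            baselineRate = 0.05, poolSize = 20,
                            taxa = c(101L, 102L, 103L)) {
    set.seed(seed)
    targets <- vapply(effects, function(e) e$targetEc, character(1))
    if (is.null(ecs)) {
        fill <- sprintf("9.9.9.%d", seq_len(max(0, 4 - length(targets))))
        ecs <- c(targets, fill)
    }
    stopifnot(all(targets %in% ecs))
    rate1 <- stats::setNames(rep(baselineRate, length(ecs)), ecs)
    for (e in effects) rate1[e$targetEc] <- e$baselineRate
    if (sum(rate1) > 1)
        stop("EC draw rates sum above 1; lower baselineRate or pool size",
             call. = FALSE)
    rate2 <- rate1
    for (e in effects) rate2[e$targetEc] <- rate2[e$targetEc] * e$enrichmentFactor
    labels <- c(ecs, ".bg")
    prob1 <- c(rate1, 1 - sum(rate1))
    prob2 <- c(rate2, 1 - sum(rate1))          # extra mass, then renormalize
    prob2 <- prob2 / sum(prob2)

    alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    mkPep <- function(k) paste(sample(alphabet, k, replace = TRUE), collapse = "")
    pools <- list(); seen <- character(0)
    for (lb in labels) {
        p <- character(0)
        while (length(p) < poolSize) {
            cand <- mkPep(sample(8:12, 1))
            if (!cand %in% seen) { p <- c(p, cand); seen <- c(seen, cand) }
        }
        pools[[lb]] <- p
    }
    sampleText <- list(); assignment <- character(0)
    for (g in 1:2) {
        prob <- if (g == 1) prob1 else prob2
        for (s in seq_len(nSamplesPerGroup)) {
            sid <- sprintf("g%d_s%d", g, s)
            lab <- sample(labels, nPerSample, replace = TRUE, prob = prob)
            peps <- vapply(lab, function(lb)
                pools[[lb]][sample.int(poolSize, 1)], character(1),
                USE.NAMES = FALSE)
            sampleText[[sid]] <- paste0(paste(peps, collapse = "\n"), "\n")
            assignment[sid] <- sprintf("group%d", g)
        }
    }
    annRows <- c("item\tec_list\ttaxon_id")
    for (i in seq_along(ecs)) {
        tx <- taxa[((i - 1) %% length(taxa)) + 1]
        annRows <- c(annRows, sprintf("%s\t%s\t%d", pools[[ecs[i]]], ecs[i], tx))
    }
    truth <- data.frame(
        ec = targets,
        factor = vapply(effects, function(e) e$enrichmentFactor, numeric(1)),
        expectedSign = vapply(effects, function(e) e$expectedSign, numeric(1)),
        stringsAsFactors = FALSE)
    list(sampleText = sampleText, assignment = assignment,
         annotationTsv = paste0(paste(annRows, collapse = "\n"), "\n"),
         truth = truth)
}

#' The packaged 32-enzyme reference set
#'
#' The reference table of 32 short-chain fatty-acid biosynthesis enzymes
#' (butyrogenesis, propionogenesis, acetogenesis) with their EC numbers,
#' associated pathway map (or none), concordance section, whether the
#' annotation service reported them, and the direction of regulation under
#' caloric restriction expected from the original rat-microbiome study.
#' Shipped as a TSV under \code{inst/extdata}; enzymes with two EC numbers
#' carry them semicolon-separated.
#'
#' @return data.frame with columns \code{process}, \code{enzyme},
#'   \code{ec} (semicolon-separated when multiple), \code{mapId}
#'   (\code{NA} = no associated pathway), \code{section},
#'   \code{reported}, \code{expectedDirection}.
#' @export
table1Fixture <- function() {
    path <- system.file("extdata", "reference_enzymes.tsv",
                        package = "MetaPathDA", mustWork = TRUE)
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            na.strings = "None")
    names(df) <- c("process", "enzyme", "ec", "mapId", "section",
                   "reported", "expectedDirection")
    df$reported <- df$reported == "yes"
    df
}
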