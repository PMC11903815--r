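# Shared fixtures, all built in code.

# a small hand-written pathway: 2 enzyme boxes (one with two ECs), 3
# compounds, a neighbouring-map link, 2 reactions and a maplink relation
toyKGML <- function() {
    paste0(
        '<?xml version="1.0"?>\n',
        '<pathway name="path:map00650" title="Butanoate metabolism" category="Metabolism">\n',
        '  <entry id="1" name="cpd:C00024" type="compound">\n',
        '    <graphics name="C00024" x="100" y="100" width="8" height="8"/>\n',
        '  </entry>\n',
        '  <entry id="2" name="ec:2.3.1.9" type="enzyme" reaction="rn:R00238">\n',
        '    <graphics name="2.3.1.9" x="170" y="100" width="46" height="17"/>\n',
        '  </entry>\n',
        '  <entry id="3" name="cpd:C00332" type="compound">\n',
        '    <graphics name="C00332" x="240" y="100" width="8" height="8"/>\n',
        '  </entry>\n',
        '  <entry id="4" name="ec:2.8.3.8 ec:2.8.3.12" type="enzyme">\n',
        '    <graphics name="2.8.3.8..." x="310" y="100" width="46" height="17"/>\n',
        '  </entry>\n',
        '  <entry id="5" name="cpd:C00246" type="compound">\n',
        '    <graphics name="C00246" x="380" y="100" width="8" height="8"/>\n',
        '  </entry>\n',
        '  <entry id="6" name="path:map00640" type="map">\n',
        '    <graphics name="Propanoate metabolism" x="460" y="100" width="90" height="25"/>\n',
        '  </entry>\n',
        '  <reaction id="2" type="reversible">\n',
        '    <substrate id="1"/>\n',
        '    <product id="3"/>\n',
        '  </reaction>\n',
        '  <reaction id="4" type="irreversible">\n',
        '    <substrate id="3"/>\n',
        '    <product id="5"/>\n',
        '  </reaction>\n',
        '  <relation entry1="5" entry2="6" type="maplink"/>\n',
        '</pathway>\n')
}

# a second, unrelated pathway so ranking/filter tests have >1 map
toyKGML2 <- function() {
    paste0(
        '<?xml version="1.0"?>\n',
        '<pathway name="path:map00720" title="Carbon fixation pathways in prokaryotes" category="Metabolism">\n',
        '  <entry id="1" name="cpd:C00036" type="compound">\n',
        '    <graphics name="C00036" x="80" y="60" width="8" height="8"/>\n',
        '  </entry>\n',
        '  <entry id="2" name="ec:1.1.1.37" type="enzyme">\n',
        '    <graphics name="1.1.1.37" x="150" y="60" width="46" height="17"/>\n',
        '  </entry>\n',
        '  <entry id="3" name="cpd:C00149" type="compound">\n',
        '    <graphics name="C00149" x="220" y="60" width="8" height="8"/>\n',
        '  </entry>\n',
        '  <reaction id="2" type="reversible">\n',
        '    <substrate id="1"/>\n',
        '    <product id="3"/>\n',
        '  </reaction>\n',
        '</pathway>\n')
}

toyTaxonomyTsv <- function() {
    paste(
        "taxon_id\tparent_id\trank\tname",
        "1\t1\tno rank\troot",
        "2\t1\tsuperkingdom\tBacteria",
        "816\t2\tgenus\tBacteroides",
        "817\t816\tspecies\tBacteroides fragilis",
        "818\t816\tspecies\tBacteroides thetaiotaomicron",
        "1386\t2\tgenus\tBacillus",
        "1396\t1386\tspecies\tBacillus cereus",
        sep = "\n")
}

toyResolverTsv <- function() {
    paste(
        "item\tec_list\ttaxon_id\tko_list",
        "AAK\t2.3.1.9\t817",
        "MLK\t2.3.1.9;2.8.3.8\t818\tK00626",
        "CCK\t1.1.1.37\t1396",
        "TTK\t2.8.3.-\t816",
        "WWK\t9.9.9.9\t2",
        sep = "\n")
}

# a two-group peptide analysis over the two toy pathways
toyAnalysis <- function(unique = FALSE) {
    s1 <- parsePeptides("AAK\nAAK\nMLK\nQQQK\n", "s1")$entries
    s2 <- parsePeptides("CCK\nTTK\nAAK\n", "s2")$entries
    gs <- assembleGroups(list(s1 = s1, s2 = s2),
                         c(s1 = "g1", s2 = "g2"), "peptide", unique = unique)
    res <- loadFixtureResolver(toyResolverTsv(), "peptide")
    ann <- annotateItems(unique(entryTable(gs)$item), res)
    pws <- list(parseKGML(toyKGML()), parseKGML(toyKGML2()))
    buildMappingIndex(gs, ann, pws)
}

# a synthetic peptide encoding an EC string with residue letters only
ecPeptide <- function(ec) paste0("PEPT", chartr("0123456789.-", "ACDEFGHIKLMN", ec))

# brute-force transitive closure oracle: items x ECs x nodes x pathways
bruteForceClosure <- function(itemEcs, weights, pathways) {
    counts <- stats::setNames(numeric(length(pathways)),
                              vapply(pathways, mapId, character(1)))
    itemMaps <- stats::setNames(list(), character(0))
    for (it in names(itemEcs)) {
        reached <- character(0)
        for (p in pathways) {
            nd <- pathwayNodes(p)
            hit <- FALSE
            for (e in itemEcs[[it]])
                for (i in seq_len(nrow(nd)))
                    if (nd$kind[i] == "enzyme")
                        for (ne in nd$ec[[i]])
                            if (ecMatches(e, ne)) hit <- TRUE
            if (hit) reached <- c(reached, mapId(p))
        }
        if (length(reached)) {
            itemMaps[[it]] <- sort(reached)
            counts[reached] <- counts[reached] + weights[[it]]
        }
    }
    list(itemToPathways = itemMaps, counts = counts)
}

# size-safe sample: never recycles a length-1 vector, caps k at length(v)
pick <- function(v, k) v[sample.int(length(v), min(k, length(v)))]

# random small mapping instance for property tests
randomInstance <- function(seed) {
    set.seed(seed)
    nEc <- sample(1:5, 1)
    ecPool <- sprintf("9.%d.%d.%d", sample(1:3, nEc, TRUE),
                      sample(1:5, nEc, TRUE), seq_len(nEc))
    nPw <- sample(1:3, 1)
    pathways <- lapply(seq_len(nPw), function(k) {
        nEnz <- sample(1:3, 1)
        entries <- character(0)
        for (i in seq_len(nEnz)) {
            ecs <- pick(ecPool, sample(1:2, 1))
            entries <- c(entries, sprintf(
                '<entry id="%d" name="%s" type="enzyme"><graphics name="e%d" x="%d" y="40" width="46" height="17"/></entry>',
                i, paste(paste0("ec:", ecs), collapse = " "), i, 50 * i))
        }
        parseKGML(sprintf(
            '<pathway name="path:map9%04d" title="rp%d" category="Synthetic">%s</pathway>',
            seed %% 1000 * 10 + k, k, paste(entries, collapse = "")))
    })
    nItems <- sample(1:10, 1)
    items <- paste0("PEPT", strsplit("ACDEFGHIKL", "")[[1]][seq_len(nItems)])
    itemEcs <- lapply(seq_len(nItems), function(i)
        pick(ecPool, sample(0:2, 1)))
    names(itemEcs) <- items
    itemEcs <- itemEcs[lengths(itemEcs) > 0]
    weights <- stats::setNames(sample(1:3, nItems, TRUE), items)
    list(items = items, itemEcs = itemEcs, weights = weights,
         pathways = pathways)
}

# assemble a SampleGroupSet whose items carry the given weights (1 group)
groupSetFromWeights <- function(weights) {
    text <- paste(rep(names(weights), times = weights), collapse = "\n")
    e <- parsePeptides(text, "s1")$entries
    assembleGroups(list(s1 = e), c(s1 = "g1"), "peptide")
}
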