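test_that("KGML parsing builds the typed node and edge model", {
    p <- parseKGML(toyKGML())
    expect_s4_class(p, "PathwayGraph")
    expect_equal(mapId(p), "map00650")
    expect_equal(pathwayName(p), "Butanoate metabolism")
    nd <- pathwayNodes(p)
    expect_equal(nrow(nd), 6L)
    expect_equal(sum(nd$kind == "enzyme"), 2L)
    expect_equal(sum(nd$kind == "compound"), 3L)
    expect_equal(sum(nd$kind == "maplink"), 1L)

    # multi-EC token split on one enzyme box
    expect_equal(sort(nd$ec[[which(nd$nodeId == 4)]]), c("2.8.3.12", "2.8.3.8"))
    # maplink prefix strip
    expect_equal(nd$linkedMapId[nd$kind == "maplink"], "map00640")
    # reaction attribute strip
    expect_equal(nd$reactions[[which(nd$nodeId == 2)]], "R00238")
    # geometry preserved verbatim (box centres)
    expect_equal(nd$x[nd$nodeId == 2], 170)
    expect_equal(nd$height[nd$nodeId == 2], 17)

    ed <- pathwayEdges(p)
    expect_equal(sum(ed$kind == "reaction"), 2L)
    expect_equal(sum(ed$kind == "maplink"), 1L)
    expect_equal(ed$direction[ed$from == 1], "bidirectional")
    expect_equal(ed$direction[ed$from == 3 & ed$kind == "reaction"], "directed")
})

test_that("minimal KGML: 1 enzyme + 2 compounds joined by a reaction", {
    xml <- paste0(
        '<pathway name="path:map00001" title="mini">',
        '<entry id="1" name="cpd:C00001" type="compound">',
        '<graphics name="C00001" x="10" y="10" width="8" height="8"/></entry>',
        '<entry id="2" name="ec:2.3.1.9" type="enzyme">',
        '<graphics name="2.3.1.9" x="50" y="10" width="46" height="17"/></entry>',
        '<entry id="3" name="cpd:C00002" type="compound">',
        '<graphics name="C00002" x="90" y="10" width="8" height="8"/></entry>',
        '<reaction id="2" type="irreversible">',
        '<substrate id="1"/><product id="3"/></reaction>',
        '</pathway>')
    p <- parseKGML(xml)
    expect_equal(nrow(pathwayNodes(p)), 3L)
    expect_equal(nrow(pathwayEdges(p)), 1L)
    expect_equal(pathwayEdges(p)$kind, "reaction")
})

test_that("missing graphics warns and keeps null geometry; dangling ids error", {
    xml <- paste0(
        '<pathway name="path:map00002" title="t">',
        '<entry id="1" name="ec:1.1.1.1" type="enzyme"/>',
        '</pathway>')
    expect_warning(p <- parseKGML(xml), "no graphics")
    expect_true(is.na(pathwayNodes(p)$x[1]))

    bad <- paste0(
        '<pathway name="path:map00003" title="t">',
        '<entry id="1" name="cpd:C00001" type="compound">',
        '<graphics name="c" x="1" y="1" width="8" height="8"/></entry>',
        '<reaction id="9" type="reversible">',
        '<substrate id="1"/><product id="99"/></reaction>',
        '</pathway>')
    expect_error(parseKGML(bad), "99")
})

test_that("serialize/re-parse round-trips to an isomorphic graph", {
    for (src in list(toyKGML(), toyKGML2(), generatePathway(4, 5, seed = 3)$kgml)) {
        p1 <- parseKGML(src)
        p2 <- parseKGML(writeKGML(p1))
        expect_equal(mapId(p2), mapId(p1))
        expect_equal(pathwayName(p2), pathwayName(p1))
        expect_equal(pathwayCategory(p2), pathwayCategory(p1))
        n1 <- pathwayNodes(p1); n2 <- pathwayNodes(p2)
        o1 <- order(n1$nodeId); o2 <- order(n2$nodeId)
        expect_equal(n1[o1, ], n2[o2, ], ignore_attr = TRUE)
        e1 <- pathwayEdges(p1); e2 <- pathwayEdges(p2)
        key <- function(e) sort(paste(e$from, e$to, e$kind, e$direction))
        expect_equal(key(e1), key(e2))
    }
})

test_that("link tables aggregate with set semantics and validate keys", {
    lt <- loadLinkTables(
        ecToMaps = "2.3.1.9\tmap00650\n1.1.1.37\tmap00720\n")
    expect_length(lt@ecToMaps, 2)
    expect_equal(lt@ecToMaps[["2.3.1.9"]], "map00650")

    # duplicate rows collapse
    lt2 <- loadLinkTables(ecToMaps = "2.3.1.9\tmap00650\n2.3.1.9\tmap00650\n")
    expect_equal(lt2@ecToMaps[["2.3.1.9"]], "map00650")

    # absent EC gives an empty set on query
    expect_null(lt@ecToMaps[["9.9.9.9"]])

    expect_error(loadLinkTables(ecToMaps = "not-an-ec\tmap00001\n"), "row 1")
})

test_that("EC node index covers every enzyme node under each of its ECs", {
    p <- parseKGML(toyKGML())
    idx <- ecNodeIndex(p)
    expect_equal(idx[["2.3.1.9"]], 2L)
    expect_equal(idx[["2.8.3.8"]], 4L)
    # exhaustive completeness scan
    nd <- pathwayNodes(p)
    for (i in which(nd$kind == "enzyme"))
        for (e in nd$ec[[i]])
            expect_true(nd$nodeId[i] %in% idx[[e]])
    # compound/maplink nodes never indexed
    expect_false(any(unlist(idx) %in% nd$nodeId[nd$kind != "enzyme"]))

    # two nodes sharing an EC map to both ids
    xml <- paste0(
        '<pathway name="path:map00004" title="t">',
        '<entry id="1" name="ec:4.2.1.17" type="enzyme">',
        '<graphics name="a" x="1" y="1" width="4" height="4"/></entry>',
        '<entry id="2" name="ec:4.2.1.17" type="enzyme">',
        '<graphics name="b" x="9" y="1" width="4" height="4"/></entry>',
        '</pathway>')
    expect_equal(ecNodeIndex(parseKGML(xml))[["4.2.1.17"]], c(1L, 2L))
})

test_that("wildcard node lookup equals a brute-force prefix scan", {
    p <- parseKGML(toyKGML())
    idx <- ecNodeIndex(p)
    nd <- pathwayNodes(p)
    brute <- sort(unique(unlist(lapply(which(nd$kind == "enzyme"), function(i)
        if (any(startsWith(nd$ec[[i]], "2.8.3."))) nd$nodeId[i] else NULL))))
    expect_equal(ecLookupNodes(idx, "2.8.3.-"), brute)
    expect_equal(ecLookupNodes(idx, "2.3.1.9"), 2L)
    expect_equal(ecLookupNodes(idx, "5.5.5.5"), integer(0))
})
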