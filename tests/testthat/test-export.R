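readCsv <- function(text) read.csv(text = text, stringsAsFactors = FALSE,
                                   colClasses = "character")

test_that("dense export is one row per (item, EC, pathway) with completeness", {
    # 1 item, 2 ECs, each found in the one shared pathway -> 2 rows
    e <- parsePeptides("AAK\n", "s1")$entries
    gs <- assembleGroups(list(s1 = e), c(s1 = "g1"), "peptide")
    ann <- list(AAK = list(ec = c("2.3.1.9", "2.8.3.8"), taxonId = NA_integer_,
                           ko = character(0)))
    idx <- buildMappingIndex(gs, ann, parseKGML(toyKGML()))
    df <- readCsv(exportDense(idx))
    expect_equal(nrow(df), 2L)
    expect_equal(df$map_id, c("map00650", "map00650"))
    expect_equal(df$pathway_name, rep("Butanoate metabolism", 2))

    # unmapped item appears with empty EC/pathway columns
    idx2 <- toyAnalysis()
    df2 <- readCsv(exportDense(idx2))
    qqq <- df2[df2$item == "QQQK", ]
    expect_equal(nrow(qqq), 1L)
    expect_equal(qqq$ec, "")
    expect_equal(qqq$map_id, "")
    # every uploaded (item, sample) pair is represented
    ent <- entryTable(idx2)
    expect_setequal(unique(paste(df2$item, df2$sample_id)),
                    unique(paste(ent$item, ent$sampleId)))

    # re-export is byte-identical
    expect_identical(exportDense(idx2), exportDense(idx2))
})

test_that("dense export quotes RFC-4180 style", {
    e <- parsePeptides("AAK\n", "s1")$entries
    gs <- assembleGroups(list(s1 = e), c(s1 = "g1"), "peptide")
    ann <- list(AAK = list(ec = "2.3.1.9", taxonId = NA_integer_, ko = character(0)))
    xml <- sub('title="Butanoate metabolism"',
               'title="A, &quot;quoted&quot; name"', toyKGML())
    idx <- buildMappingIndex(gs, ann, parseKGML(xml))
    csv <- exportDense(idx)
    expect_match(csv, '"A, ""quoted"" name"', fixed = TRUE)
    expect_equal(readCsv(csv)$pathway_name[1], 'A, "quoted" name')
})

test_that("pathway list export is ordered with the zero tail and all rows", {
    idx <- toyAnalysis()
    r <- rankPathways(idx)
    df <- readCsv(exportPathwayList(r))
    expect_equal(nrow(df), length(pathwayList(idx)))
    expect_equal(df$map_id, r$mapId)
    expect_equal(as.numeric(df$match_count), r$count)
    expect_true(all(diff(as.numeric(df$match_count)) <= 0))
})

test_that("node comparison export serializes sentinels as +inf/-inf/NA", {
    cmp <- data.frame(nodeId = 1:4, label = letters[1:4],
                      x = c(1, 0, 2, 0), p1 = 10, y = c(2, 3, 0, 0), p2 = 10,
                      daRaw = c(0.5, Inf, -Inf, NaN),
                      daNorm = c(1, 1, -1, NA))
    csv <- exportNodeComparison(cmp)
    expect_match(csv, "\\+inf")
    expect_match(csv, "-inf")
    lines <- strsplit(csv, "\n")[[1]]
    expect_equal(strsplit(lines[5], ",")[[1]][7], "NA")
})

test_that("DA overlay is well-formed SVG with one rect per highlighted node + legend", {
    idx <- toyAnalysis()
    cmp <- comparePathway(idx, "map00650")
    svg <- renderOverlay(pathwayList(idx)[["map00650"]], comparison = cmp)
    doc <- xml2::read_xml(svg)   # parses => well-formed
    rects <- xml2::xml_find_all(doc, "//*[local-name()='rect']")
    highlighted <- sum(cmp$x > 0 | cmp$y > 0)
    expect_equal(length(rects), highlighted + 1L)   # + legend bar

    # midpoint color: daNorm 0 renders the middle colormap stop (white)
    cmp0 <- cmp
    cmp0$daRaw <- 0; cmp0$daNorm <- 0
    svg0 <- renderOverlay(pathwayList(idx)[["map00650"]], comparison = cmp0)
    expect_match(svg0, 'fill="#FFFFFF"')

    # rectangles sit at (x - width/2, y - height/2): node 2 box 170,100 46x17
    expect_match(svg, '<rect x="147" y="91.5" width="46" height="17"')
})

test_that("presence overlay splits node boxes into equal per-group segments", {
    idx <- toyAnalysis()
    seg <- presenceSegments(idx, "map00650")
    svg <- renderOverlay(pathwayList(idx)[["map00650"]], segments = seg)
    doc <- xml2::read_xml(svg)
    rects <- xml2::xml_find_all(doc, "//*[local-name()='rect']")
    expect_equal(length(rects), sum(vapply(seg, sum, integer(1))))
    # node 2 matched by both of 2 groups: two half-width segments
    expect_match(svg, 'width="23"')

    # a node with only one of two groups matched gets one half-width segment
    seg1 <- list(`2` = c(g1 = TRUE, g2 = FALSE))
    svg1 <- renderOverlay(pathwayList(idx)[["map00650"]], segments = seg1)
    r1 <- xml2::xml_find_all(xml2::read_xml(svg1), "//*[local-name()='rect']")
    expect_equal(length(r1), 1L)
})

test_that("overlay skips geometry-less nodes with a warning", {
    xml <- paste0(
        '<pathway name="path:map00009" title="t">',
        '<entry id="1" name="ec:1.1.1.1" type="enzyme"/>',
        '<entry id="2" name="ec:2.2.2.2" type="enzyme">',
        '<graphics name="b" x="50" y="50" width="40" height="16"/></entry>',
        '</pathway>')
    p <- suppressWarnings(parseKGML(xml))
    cmp <- data.frame(nodeId = c(1L, 2L), label = c("a", "b"),
                      x = c(1, 1), p1 = 10, y = c(2, 2), p2 = 10,
                      daRaw = c(0.1, 0.1), daNorm = c(1, 1))
    expect_warning(svg <- renderOverlay(p, comparison = cmp), "no geometry")
    rects <- xml2::xml_find_all(xml2::read_xml(svg), "//*[local-name()='rect']")
    expect_equal(length(rects), 2L)   # one node + legend
})
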