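test_that("index counts items once per pathway, weighted by multiplicity", {
    # 1 peptide x3 with one EC present in one pathway -> count 3
    e <- parsePeptides("AAK\nAAK\nAAK\n", "s1")$entries
    gs <- assembleGroups(list(s1 = e), c(s1 = "g1"), "peptide")
    ann <- list(AAK = list(ec = "2.3.1.9", taxonId = NA_integer_, ko = character(0)))
    idx <- buildMappingIndex(gs, ann, parseKGML(toyKGML()))
    expect_equal(unname(pathwayMatchCounts(idx)["map00650"]), 3)

    # item with two ECs hitting the same pathway still counts once
    ann2 <- list(AAK = list(ec = c("2.3.1.9", "2.8.3.8"), taxonId = NA_integer_,
                            ko = character(0)))
    idx2 <- buildMappingIndex(gs, ann2, parseKGML(toyKGML()))
    expect_equal(unname(pathwayMatchCounts(idx2)["map00650"]), 3)
    # ... but reaches both nodes
    expect_equal(sort(idx2@nodeHits$nodeId), c(2L, 4L))
})

test_that("index equals the brute-force transitive closure on random instances", {
    for (seed in 1:60) {
        inst <- randomInstance(seed)
        gs <- groupSetFromWeights(inst$weights)
        ann <- lapply(inst$itemEcs, function(e)
            list(ec = e, taxonId = NA_integer_, ko = character(0)))
        idx <- buildMappingIndex(gs, ann, inst$pathways)
        oracle <- bruteForceClosure(inst$itemEcs, inst$weights, inst$pathways)
        expect_equal(idx@itemToPathways[order(names(idx@itemToPathways))],
                     oracle$itemToPathways[order(names(oracle$itemToPathways))])
        expect_equal(pathwayMatchCounts(idx)[names(oracle$counts)],
                     oracle$counts)
    }
})

test_that("ranking is descending with map-id tie-break and a zero tail", {
    idx <- toyAnalysis()
    r <- rankPathways(idx)
    expect_true(all(diff(r$count) <= 0))
    # adding matches never decreases counts (monotonicity across samples)
    s1 <- parsePeptides("AAK\nAAK\nMLK\nQQQK\n", "s1")$entries
    gs1 <- assembleGroups(list(s1 = s1), c(s1 = "g1"), "peptide")
    res <- loadFixtureResolver(toyResolverTsv(), "peptide")
    pws <- list(parseKGML(toyKGML()), parseKGML(toyKGML2()))
    idx1 <- buildMappingIndex(gs1, annotateItems(unique(entryTable(gs1)$item), res), pws)
    r1 <- rankPathways(idx1)
    expect_true(all(r$count[match(r1$mapId, r$mapId)] >= r1$count))

    # tie-break by ascending map id, zero-match pathways kept at the tail
    e <- parsePeptides("AAK\n", "s1")$entries
    gs <- assembleGroups(list(s1 = e), c(s1 = "g1"), "peptide")
    ann <- list(AAK = list(ec = c("2.3.1.9", "1.1.1.37"), taxonId = NA_integer_,
                           ko = character(0)))
    both <- buildMappingIndex(gs, ann, pws)
    rb <- rankPathways(both)
    expect_equal(rb$mapId, c("map00650", "map00720"))   # tie at 1, id order
    none <- buildMappingIndex(gs, list(AAK = list(ec = "5.5.5.5",
                                                  taxonId = NA_integer_,
                                                  ko = character(0))), pws)
    rn <- rankPathways(none)
    expect_equal(rn$count, c(0, 0))
    expect_equal(nrow(rn), 2L)
})

test_that("pathway filters conjoin and preserve order", {
    idx <- toyAnalysis()
    r <- rankPathways(idx)
    # identity: no criteria returns the input
    expect_equal(filterPathways(idx, r), r)
    # text filter over name, case-insensitive
    expect_equal(filterPathways(idx, r, text = "butanoate")$mapId, "map00650")
    # content filters test pathway content, not user matches
    expect_equal(filterPathways(idx, r, requiredEcs = "2.3.1.9")$mapId, "map00650")
    expect_equal(filterPathways(idx, r, requiredCompounds = "C00036")$mapId,
                 "map00720")
    # conjunction law: combined = intersection of single-criterion results
    a <- filterPathways(idx, r, text = "metabolism")$mapId
    b <- filterPathways(idx, r, requiredEcs = "1.1.1.37")$mapId
    ab <- filterPathways(idx, r, text = "metabolism", requiredEcs = "1.1.1.37")$mapId
    expect_equal(ab, intersect(a, b))
    # empty result is legal
    expect_equal(nrow(filterPathways(idx, r, text = "no such pathway")), 0L)
})

test_that("offered filter options each lead to at least one result", {
    idx <- toyAnalysis()
    r <- rankPathways(idx)
    opts <- availableFilterOptions(idx)
    for (e in opts$ec)
        expect_gt(nrow(filterPathways(idx, r, requiredEcs = e)), 0)
    for (cc in opts$compound)
        expect_gt(nrow(filterPathways(idx, r, requiredCompounds = cc)), 0)
    # brute-force union over pathways equals the offered set
    ecs <- character(0); cpds <- character(0)
    for (p in pathwayList(idx)) {
        nd <- pathwayNodes(p)
        ecs <- c(ecs, unlist(nd$ec[nd$kind == "enzyme"]))
        cpds <- c(cpds, nd$compoundId[nd$kind == "compound"])
    }
    expect_equal(opts$ec, sort(unique(ecs)))
    expect_equal(opts$compound, sort(unique(cpds)))
    # an EC present in no pathway is not offered
    expect_false("5.5.5.5" %in% opts$ec)
})

test_that("LCA summarizes node taxonomy; singletons and siblings behave", {
    tax <- loadTaxonomy(toyTaxonomyTsv())
    expect_equal(taxonLCA(tax, 817L), 817L)
    expect_equal(taxonLCA(tax, c(817L, 818L)), 816L)       # siblings -> parent
    expect_equal(taxonLCA(tax, c(817L, 1396L)), 2L)        # across genera
    expect_error(taxonLineage(tax, 999L), "999")

    # brute-force lineage-intersection oracle on random taxon sets
    ids <- taxonTable(tax)$taxonId
    for (seed in 1:20) {
        set.seed(seed)
        s <- sample(ids, sample(1:4, 1))
        lins <- lapply(s, function(t) taxonLineage(tax, t))
        common <- Reduce(intersect, lins)
        # deepest common ancestor = the first element of any lineage that
        # every other lineage contains
        expect_equal(taxonLCA(tax, s), common[1])
        # idempotence and commutativity
        expect_equal(taxonLCA(tax, c(s, taxonLCA(tax, s))), taxonLCA(tax, s))
        expect_equal(taxonLCA(tax, rev(s)), taxonLCA(tax, s))
    }
})

test_that("per-node taxon summary is the LCA of matching items' taxa", {
    idx <- toyAnalysis()
    tax <- loadTaxonomy(toyTaxonomyTsv())
    # node 2 (EC 2.3.1.9) matched by AAK (817) and MLK (818): LCA is genus 816
    got <- nodeTaxonSummary(idx, "map00650", 2L, tax)
    expect_equal(got$taxonId, 816L)
    expect_equal(got$rank, "genus")
    expect_equal(got$name, "Bacteroides")
    # node with no matched taxon-bearing item is absent
    expect_null(nodeTaxonSummary(idx, "map00650", 1L, tax))
})
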