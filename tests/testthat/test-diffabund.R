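test_that("peptide DA matches hand evaluation, antisymmetry and the unit bound", {
    expect_equal(daPeptides(2, 10, 2, 10), 0.0)
    expect_equal(daPeptides(2, 10, 3, 10), 0.1)
    expect_error(daPeptides(1, 0, 1, 10), "denominator")
    expect_error(daPeptides(5, 4, 1, 10), "counts")

    # exhaustive small-integer grid: bound and antisymmetry
    for (p1 in 1:5) for (p2 in 1:5) for (x in 0:p1) for (y in 0:p2) {
        v <- daPeptides(x, p1, y, p2)
        expect_equal(v, y / p2 - x / p1)
        expect_lte(abs(v), 1)
        expect_equal(daPeptides(y, p2, x, p1), -v)
    }
})

test_that("protein DA is a log2 fold-change with explicit sentinels", {
    expect_equal(daProteins(4, 2, 8, 2), 1.0)
    expect_equal(daProteins(3, 7, 3, 7), 0.0)
    expect_equal(daProteins(0, 2, 5, 2), Inf)
    expect_equal(daProteins(5, 2, 0, 2), -Inf)
    expect_true(is.nan(daProteins(0, 2, 0, 2)))
    expect_error(daProteins(1, 1, 1, 1, pseudocount = -1), "pseudocount")
    # pseudocount defuses the zero sentinel
    expect_true(is.finite(daProteins(0, 2, 5, 2, pseudocount = 0.5)))

    # random tuples: hand formula, antisymmetry (sentinels swap), scale invariance
    set.seed(42)
    for (i in 1:100) {
        x <- sample(0:20, 1); y <- sample(0:20, 1)
        p1 <- runif(1, 1, 50); p2 <- runif(1, 1, 50)
        v <- daProteins(x, p1, y, p2)
        if (x > 0 && y > 0)
            expect_equal(v, log2((y / p2) / (x / p1)))
        sw <- daProteins(y, p2, x, p1)
        if (is.nan(v)) expect_true(is.nan(sw)) else expect_equal(sw, -v)
        c <- runif(1, 0.1, 10)
        expect_equal(daProteins(c * x, c * p1, c * y, c * p2), v)
    }
})

test_that("diverging normalization scales each side by its own maximum", {
    expect_equal(normalizeDiverging(c(-0.2, 0.0, 0.8)), c(-1, 0, 1))
    expect_equal(normalizeDiverging(c(0.4, 0.8)), c(0.5, 1))
    expect_equal(normalizeDiverging(c(0, 0, 0)), c(0, 0, 0))
    # sentinels: infinities pin to the ends, undefined stays NA
    expect_equal(normalizeDiverging(c(Inf, -Inf, 0.5, NaN)),
                 c(1, -1, 1, NA_real_))
    # infinities are excluded from scale estimation: 0.5 still maps to 1
    expect_equal(normalizeDiverging(c(Inf, 0.25, 0.5))[2], 0.5)

    # randomized properties: range, midpoint, per-side monotonicity
    set.seed(7)
    for (i in 1:50) {
        v <- round(runif(sample(2:12, 1), -5, 5), 2)
        mid <- round(runif(1, -1, 1), 2)
        n <- normalizeDiverging(v, mid)
        expect_true(all(n >= -1 & n <= 1, na.rm = TRUE))
        expect_equal(n[v == mid], rep(0, sum(v == mid)))
        if (any(v > mid)) expect_equal(max(n[v > mid]), 1)
        if (any(v < mid)) expect_equal(min(n[v < mid]), -1)
        o <- order(v)
        expect_true(all(diff(n[o]) >= -1e-12))   # monotone overall per side
    }
})

test_that("pathway comparison assembles per-node counts and normalizes per view", {
    idx <- toyAnalysis()
    cmp <- comparePathway(idx, "map00650")
    expect_equal(sort(cmp$nodeId), c(2L, 4L))
    # group totals are the assembled denominators
    expect_equal(unique(cmp$p1), 4)   # AAK x2 + MLK + QQQK
    expect_equal(unique(cmp$p2), 3)
    # node 2 (2.3.1.9): AAK w1=2 w2=1, MLK w1=1 -> x=3, y=1
    n2 <- cmp[cmp$nodeId == 2, ]
    expect_equal(c(n2$x, n2$y), c(3, 1))
    expect_equal(n2$daRaw, daPeptides(3, 4, 1, 3))
    # node 4 (2.8.3.*): MLK w1=1; TTK w2=1
    n4 <- cmp[cmp$nodeId == 4, ]
    expect_equal(c(n4$x, n4$y), c(1, 1))
    expect_equal(cmp$daNorm, normalizeDiverging(cmp$daRaw))

    # node matched only in group 2 gets positive DA
    e1 <- parsePeptides("QQQK\n", "a")$entries
    e2 <- parsePeptides("AAK\n", "b")$entries
    gs <- assembleGroups(list(a = e1, b = e2), c(a = "g1", b = "g2"), "peptide")
    ann <- list(AAK = list(ec = "2.3.1.9", taxonId = NA_integer_, ko = character(0)))
    only2 <- comparePathway(buildMappingIndex(gs, ann, parseKGML(toyKGML())),
                            "map00650")
    expect_gt(only2$daRaw[only2$nodeId == 2], 0)

    # identical groups give all-zero DA
    gsEq <- assembleGroups(list(a = e2, b = e2), c(a = "g1", b = "g2"), "peptide")
    eq <- comparePathway(buildMappingIndex(gsEq, ann, parseKGML(toyKGML())),
                         "map00650")
    expect_equal(eq$daRaw, rep(0, nrow(eq)))

    # single-group analysis refuses the DA view
    g1 <- assembleGroups(list(a = e2), c(a = "g1"), "peptide")
    i1 <- buildMappingIndex(g1, ann, parseKGML(toyKGML()))
    expect_error(comparePathway(i1, "map00650"), "2 groups")
    expect_error(comparePathway(idx, "map99999"), "unknown pathway")
})

test_that("swapping group order negates per-node peptide DA", {
    s1 <- parsePeptides("AAK\nAAK\nMLK\n", "s1")$entries
    s2 <- parsePeptides("AAK\nTTK\n", "s2")$entries
    res <- loadFixtureResolver(toyResolverTsv(), "peptide")
    pw <- parseKGML(toyKGML())
    mk <- function(samples) {
        # group order follows first occurrence across the sample list, so
        # reversing the list swaps which group is "group 1" of the formulas
        gs <- assembleGroups(samples,
                             c(s1 = "gA", s2 = "gB")[names(samples)], "peptide")
        idx <- buildMappingIndex(gs, annotateItems(unique(entryTable(gs)$item), res), pw)
        comparePathway(idx, "map00650")
    }
    fwd <- mk(list(s1 = s1, s2 = s2))
    swapped <- mk(list(s2 = s2, s1 = s1))
    o <- match(fwd$nodeId, swapped$nodeId)
    expect_equal(swapped$daRaw[o], -fwd$daRaw)
})

test_that("presence segments flag per-group matches and omit unmatched nodes", {
    idx <- toyAnalysis()
    seg <- presenceSegments(idx, "map00650")
    # node 2: AAK in both groups, MLK in g1 -> (TRUE, TRUE)
    expect_equal(unname(seg[["2"]]), c(TRUE, TRUE))
    # node 4: MLK (g1), TTK (g2) -> both
    expect_equal(unname(seg[["4"]]), c(TRUE, TRUE))
    # unmatched nodes omitted entirely
    expect_named(seg, c("2", "4"), ignore.order = TRUE)

    # single-group: one full-width segment flag
    e <- parsePeptides("AAK\n", "a")$entries
    gs <- assembleGroups(list(a = e), c(a = "only"), "peptide")
    ann <- list(AAK = list(ec = "2.3.1.9", taxonId = NA_integer_, ko = character(0)))
    s1g <- presenceSegments(buildMappingIndex(gs, ann, parseKGML(toyKGML())),
                            "map00650")
    expect_equal(unname(s1g[["2"]]), TRUE)
})
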