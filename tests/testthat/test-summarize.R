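## Build a scaffold of n fragments and a best-hit table assigning the first
## nBact fragments to a bacterial leaf and the next nEuk to an algal leaf;
## remaining fragments get no hit.
votingFixture <- function(n, nBact, nEuk, id = "sc") {
    fr <- fragmentScaffold(strrep("ACGT", 125L * n), 500, id = id)
    withHit <- seq_len(nBact + nEuk)
    best <- fakeBestHits(names(fr)[withHit],
                         c(rep(109578L, nBact), rep(2880L, nEuk)))
    list(fragments = fr, best = best)
}

test_that("a 26% bacterial / 74% algal scaffold is ambiguous", {
    ## 557 resolved hits, 26% bacterial
    fx <- votingFixture(557, nBact = 145, nEuk = 412)
    s <- summarizeScaffold(fx$fragments, fx$best, taxTree, twoCladeConfig)
    expect_identical(s$classification, "ambiguous")
    expect_identical(s$n_fragments_with_hit, 557L)
    expect_equal(s$pct_Bacteria, 100 * 145 / 557)
    expect_equal(s$pct_Eukaryota + s$pct_Bacteria, 100)
})

test_that("scaffolds without surviving hits are no_hits", {
    fx <- votingFixture(20, 0, 0)
    s <- summarizeScaffold(fx$fragments, fx$best[0, ], taxTree,
                           twoCladeConfig)
    expect_identical(s$classification, "no_hits")
    expect_identical(s$n_fragments_with_hit, 0L)
    expect_true(is.na(s$pct_Bacteria))
})

test_that("19 of 20 bacterial fragments classify the scaffold bacterial", {
    fx <- votingFixture(20, nBact = 19, nEuk = 1)
    s <- summarizeScaffold(fx$fragments, fx$best, taxTree, twoCladeConfig)
    expect_equal(s$pct_Bacteria, 95)
    expect_identical(s$classification, "Bacteria")
})

test_that("the 90% rule is inclusive at the boundary", {
    ## exactly 90.00% -> the clade
    fx <- votingFixture(100, nBact = 90, nEuk = 10)
    s <- summarizeScaffold(fx$fragments, fx$best, taxTree, twoCladeConfig,
                           threshold = 90)
    expect_equal(s$pct_Bacteria, 90)
    expect_identical(s$classification, "Bacteria")

    ## just below (89.9%) -> ambiguous
    fx2 <- votingFixture(1000, nBact = 899, nEuk = 101)
    s2 <- summarizeScaffold(fx2$fragments, fx2$best, taxTree,
                            twoCladeConfig, threshold = 90)
    expect_equal(s2$pct_Bacteria, 89.9)
    expect_identical(s2$classification, "ambiguous")
})

test_that("unresolved hits leave the percentage denominator", {
    fr <- fragmentScaffold(strrep("ACGT", 125L * 10L), 500, id = "u")
    best <- fakeBestHits(names(fr), c(rep(109578L, 5), rep(NA, 5)))
    s <- summarizeScaffold(fr, best, taxTree, twoCladeConfig)
    expect_identical(s$n_fragments_with_hit, 10L)
    expect_identical(s$n_unresolved, 5L)
    expect_equal(s$pct_Bacteria, 100)
    expect_identical(s$classification, "Bacteria")

    ## denominator = "clades" ignores "other" hits as well
    best2 <- fakeBestHits(names(fr), c(rep(109578L, 5), rep(1L, 5)))
    s2 <- summarizeScaffold(fr, best2, taxTree, twoCladeConfig)
    expect_equal(s2$pct_Bacteria, 50)
    s3 <- summarizeScaffold(fr, best2, taxTree, twoCladeConfig,
                            denominator = "clades")
    expect_equal(s3$pct_Bacteria, 100)
})

test_that("mixed-scaffold fragment sets are rejected", {
    fr <- c(fragmentScaffold(strrep("ACGT", 500), 500, id = "a"),
            fragmentScaffold(strrep("ACGT", 500), 500, id = "b"))
    expect_error(summarizeScaffold(fr, fakeBestHits("a__0", 2L), taxTree,
                                   twoCladeConfig), "more than one scaffold")
    fx <- votingFixture(10, 9, 1)
    expect_error(summarizeScaffold(fx$fragments, fx$best, taxTree,
                                   twoCladeConfig, threshold = 50),
                 "threshold")
})

test_that("at T > 50 with disjoint clades classification is unique, and
           raising T never promotes an ambiguous scaffold", {
    set.seed(31)
    for (i in 1:40) {
        n <- sample(5:60, 1)
        nB <- sample(0:n, 1)
        fx <- votingFixture(n, nB, n - nB)
        for (Tlow in c(60, 75, 90)) {
            s <- summarizeScaffold(fx$fragments, fx$best, taxTree,
                                   twoCladeConfig, threshold = Tlow)
            above <- sum(c(s$pct_Bacteria, s$pct_Eukaryota) >= Tlow)
            expect_lte(above, 1L)
            s99 <- summarizeScaffold(fx$fragments, fx$best, taxTree,
                                     twoCladeConfig, threshold = 99.5)
            if (s$classification == "ambiguous")
                expect_identical(s99$classification, "ambiguous")
        }
    }
})

test_that("assembly totals aggregate counts and bp per classification", {
    mk <- function(id, n, nB, nE) {
        fx <- votingFixture(n, nB, nE, id = id)
        summarizeScaffold(fx$fragments, fx$best, taxTree, twoCladeConfig)
    }
    s1 <- mk("s1", 20, 19, 1)    # Bacteria, 10 kbp
    s2 <- mk("s2", 10, 10, 0)    # Bacteria, 5 kbp
    s3 <- mk("s3", 14, 7, 7)     # ambiguous, 7 kbp
    rep <- summarizeAssembly(list(s1, s2, s3))
    t <- reportTotals(rep)
    expect_identical(t$n_scaffolds[t$classification == "Bacteria"], 2L)
    expect_equal(t$total_bp[t$classification == "Bacteria"], 15000)
    expect_equal(t$total_bp[t$classification == "ambiguous"], 7000)

    expect_error(summarizeAssembly(list()), "no scaffold")
    expect_error(summarizeAssembly(list(s1, s1)), "duplicate")
})

test_that("the TSV report round-trips and has the documented schema", {
    mk <- function(id, n, nB, nE) {
        fx <- votingFixture(n, nB, nE, id = id)
        summarizeScaffold(fx$fragments, fx$best, taxTree, twoCladeConfig)
    }
    rep <- summarizeAssembly(list(mk("sA", 20, 19, 1), mk("sB", 12, 6, 6)),
                             parameters = list(threshold = 90))
    path <- tempfile(fileext = ".tsv")
    writeReport(rep, path)
    back <- readReport(path)

    ## schema: 7 + 2 * n_clades columns
    expect_identical(ncol(back), 7L + 2L * 2L)
    expect_identical(back$scaffold_id, reportRows(rep)$scaffold_id)
    expect_identical(back$classification, reportRows(rep)$classification)
    expect_identical(back$n_Bacteria, reportRows(rep)$n_Bacteria)
    ## percentages are written with 2 decimals
    expect_equal(back$pct_Bacteria, round(reportRows(rep)$pct_Bacteria, 2))
    ## LF endings, metadata comments present
    raw <- readBin(path, "raw", file.size(path))
    expect_false(any(raw == charToRaw("\r")))
    expect_true(any(grepl("^# parameter threshold", attr(back, "comments"))))

    ## a second write of the read-back data is value-identical
    expect_identical(classifiedIds(rep, "Bacteria"), "sA")
})
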