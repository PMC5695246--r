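test_that("a narrow host composition yields a single mode near 49%", {
    set.seed(41)
    m <- demoManifest(nHost = 100, nContaminant = 0, nHybrid = 0,
                      hostLength = 20000)
    asm <- makeAssembly(m, seed = 411)$assembly
    rep <- fakeReport(m$scaffold_id, rep("Eukaryota", 100), m$length)
    d <- classGCDistribution(rep, asm, "Eukaryota")
    expect_identical(sum(d@counts), 100L)
    expect_length(gcModes(d), 1L)
    expect_lt(abs(gcModes(d) - 49), 1)
})

test_that("one scaffold gives one occupied bin and one mode", {
    asm <- makeAssembly(demoManifest(1, 0, 0), seed = 42)$assembly
    rep <- fakeReport(names(asm), "Eukaryota", Biostrings::width(asm))
    d <- classGCDistribution(rep, asm, "Eukaryota")
    expect_identical(sum(d@counts > 0), 1L)
    expect_length(gcModes(d), 1L)
    expect_error(classGCDistribution(rep, asm, "Bacteria"), "no scaffolds")
})

test_that("a planted 4-level GC mixture recovers all four modes", {
    m <- demoManifest(nHost = 0, nContaminant = 200, nHybrid = 0,
                      contaminantGC = c(0.30, 0.38, 0.53, 0.64),
                      contaminantLength = 40000)
    asm <- makeAssembly(m, seed = 412)$assembly
    rep <- fakeReport(m$scaffold_id, rep("Bacteria", 200), m$length)
    d <- classGCDistribution(rep, asm, "Bacteria")
    modes <- gcModes(d)
    expect_length(modes, 4L)
    for (lvl in c(30, 38, 53, 64))
        expect_lt(min(abs(modes - lvl)), 1)
})

test_that("bestSplit locates a planted GC junction exactly where the
           divergence is maximal", {
    set.seed(43)
    chim <- paste0(randSeq(20000, 0.30), randSeq(20000, 0.60))
    bs <- bestSplit(chim, minSegLen = 5000)
    expect_true(bs$splittable)
    expect_lt(abs(bs$position - 20000), 500)
    expect_gt(bs$score, segParams()@threshold)
    expect_equal(bs$gcLeft, 0.30, tolerance = 0.02)
    expect_equal(bs$gcRight, 0.60, tolerance = 0.02)

    ## homogeneous window: score stays below the calibrated threshold
    hom <- randSeq(40000, 0.50)
    expect_lt(bestSplit(hom, 5000)$score, segParams()@threshold)

    ## window of exactly 2*minSegLen has a single candidate position
    small <- randSeq(10000, 0.5)
    expect_identical(bestSplit(small, 5000)$position, 5000L)
    expect_false(bestSplit(randSeq(9999, 0.5), 5000)$splittable)
})

test_that("segmentation recovers planted junctions and respects
           min-length, tiling and determinism", {
    set.seed(44)
    s3 <- paste0(randSeq(50000, 0.35), randSeq(50000, 0.50),
                 randSeq(50000, 0.35))
    seg <- segmentScaffold(s3, segParams(), id = "tri")
    expect_identical(length(breakpoints(seg)), 2L)
    expect_lt(abs(breakpoints(seg)[1] - 50000), 2000)
    expect_lt(abs(breakpoints(seg)[2] - 100000), 2000)

    st <- segmentTable(seg)
    expect_identical(st$start[1], 1L)
    expect_identical(st$end[nrow(st)], 150000L)
    expect_true(all(st$start[-1] == st$end[-nrow(st)] + 1L))
    expect_true(all(st$end - st$start + 1L >= segParams()@minSegLen))
    expect_equal(st$gc, c(0.35, 0.50, 0.35), tolerance = 0.02)

    ## deterministic given (sequence, params)
    seg2 <- segmentScaffold(s3, segParams(), id = "tri")
    expect_identical(breakpoints(seg2), breakpoints(seg))
    expect_identical(segmentTable(seg2), segmentTable(seg))

    ## homogeneous scaffold: no breakpoints; short scaffold: one segment
    hom <- segmentScaffold(randSeq(60000, 0.5), segParams(), id = "h")
    expect_length(breakpoints(hom), 0L)
    short <- segmentScaffold(randSeq(5000, 0.5), segParams(), id = "s")
    expect_identical(nrow(segmentTable(short)), 1L)
    expect_identical(segmentTable(short)$halt, "min-length")
})

test_that("hybrid flagging requires differently-classified segments", {
    set.seed(45)
    ## one hybrid scaffold: 40 kb bacterial + 40 kb algal
    m <- demoManifest(nHost = 0, nContaminant = 0, nHybrid = 1)
    asm <- makeAssembly(m, seed = 451)$assembly
    frags <- fragmentAssembly(asm, 500)
    truth <- fragmentTruth(m, frags)
    best <- fakeBestHits(names(frags),
                         ifelse(truth == "Bacteria", 109578L, 2880L))
    s <- summarizeScaffold(frags, best, taxTree, twoCladeConfig)
    expect_identical(s$classification, "ambiguous")
    rep <- summarizeAssembly(list(s))
    segs <- list(segmentScaffold(asm[1]))
    names(segs) <- names(asm)
    hyb <- flagHybrids(rep, segs, frags, best, taxTree, twoCladeConfig)
    expect_identical(hyb$scaffolds$status, "hybrid")
    expect_identical(hyb$segments$classification, c("Bacteria", "Eukaryota"))

    ## taxonomically mixed but compositionally uniform: mixed-unsegmented
    m2 <- demoManifest(nHost = 1, nContaminant = 0, nHybrid = 0,
                      hostLength = 40000)
    asm2 <- makeAssembly(m2, seed = 452)$assembly
    fr2 <- fragmentAssembly(asm2, 500)
    alt <- rep(c(109578L, 2880L), length.out = length(fr2))
    best2 <- fakeBestHits(names(fr2), alt)
    s2 <- summarizeScaffold(fr2, best2, taxTree, twoCladeConfig)
    expect_identical(s2$classification, "ambiguous")
    rep2 <- summarizeAssembly(list(s2))
    segs2 <- list(segmentScaffold(asm2[1]))
    names(segs2) <- names(asm2)
    hyb2 <- flagHybrids(rep2, segs2, fr2, best2, taxTree, twoCladeConfig)
    expect_identical(hyb2$scaffolds$status, "mixed-unsegmented")

    ## segments each individually ambiguous: not flagged
    m3 <- demoManifest(nHost = 0, nContaminant = 0, nHybrid = 1,
                       contaminantGC = 0.30)
    asm3 <- makeAssembly(m3, seed = 453)$assembly
    fr3 <- fragmentAssembly(asm3, 500)
    best3 <- fakeBestHits(names(fr3),
                          rep(c(109578L, 2880L), length.out = length(fr3)))
    s3r <- summarizeScaffold(fr3, best3, taxTree, twoCladeConfig)
    rep3 <- summarizeAssembly(list(s3r))
    segs3 <- list(segmentScaffold(asm3[1]))
    names(segs3) <- names(asm3)
    expect_length(breakpoints(segs3[[1]]), 1L)
    hyb3 <- flagHybrids(rep3, segs3, fr3, best3, taxTree, twoCladeConfig)
    expect_identical(hyb3$scaffolds$status, "not-hybrid")
    expect_true(all(hyb3$segments$classification == "ambiguous"))
})
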