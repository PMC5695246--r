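test_that("length filter is strictly greater-than and reports exclusions", {
    set.seed(1)
    fa <- writeTestFasta(c(s1 = randSeq(2500), s2 = randSeq(1800)))
    asm <- suppressMessages(readAssembly(fa, minLength = 2000))
    expect_identical(names(asm), "s1")

    expect_length(suppressMessages(readAssembly(fa, minLength = 0)), 2L)

    seqs <- setNames(vapply(1:10, function(i) randSeq(1000 * i), ""),
                     paste0("sc", 1:10))
    fa10 <- writeTestFasta(seqs)
    expect_message(asm10 <- readAssembly(fa10, minLength = 2000),
                   "2 scaffold\\(s\\) excluded.*3000 bp")
    expect_length(asm10, 8L)
})

test_that("assembly reading validates ids and alphabet", {
    fa <- writeTestFasta(c(a = "ACGT", a = "ACGTAC"))
    expect_error(suppressMessages(readAssembly(fa, 0)), "duplicate.*a")

    fa2 <- writeTestFasta(c(ok = "ACGT", bad = "ACGXT"))
    expect_error(suppressMessages(readAssembly(fa2, 0)),
                 "'X' in record 'bad' at position 4")

    fa3 <- tempfile(); writeLines(character(0), fa3)
    expect_error(readAssembly(fa3, 0), "empty")

    fa4 <- writeTestFasta(c(a__1 = "ACGT"))
    expect_error(suppressMessages(readAssembly(fa4, 0)), "__")

    ## lowercase and line-wrapped input is accepted and uppercased
    fa5 <- writeTestFasta(c(s = tolower(randSeq(200))), wrap = 60)
    asm <- readAssembly(fa5, 0)
    expect_identical(as.character(asm[[1]]),
                     toupper(as.character(asm[[1]])))
})

test_that("fragmentation tiles the scaffold with a remainder tail", {
    set.seed(2)
    s <- randSeq(1234)
    fr <- fragmentScaffold(s, fragLen = 500, id = "sc")
    mc <- S4Vectors::mcols(fr)
    expect_identical(mc$start, c(0L, 500L, 1000L))
    expect_identical(mc$end, c(500L, 1000L, 1234L))
    expect_identical(names(fr), c("sc__0", "sc__1", "sc__2"))
    expect_identical(paste(as.character(fr), collapse = ""), s)

    one <- fragmentScaffold(randSeq(500), fragLen = 500, id = "x")
    expect_length(one, 1L)
    expect_identical(Biostrings::width(one), 500L)

    expect_error(fragmentScaffold(s, fragLen = 0, id = "sc"), "fragLen")
    expect_error(fragmentScaffold(s, fragLen = 500), "id")
})

test_that("a 504,453 bp scaffold yields 1,009 fragments, last of 453 bp", {
    set.seed(3)
    fr <- fragmentScaffold(randSeq(504453), fragLen = 500, id = "sc159")
    expect_length(fr, 1009L)
    expect_identical(Biostrings::width(fr)[1009], 453L)
    expect_identical(sum(Biostrings::width(fr)), 504453L)
})

test_that("fragment count equals ceiling(length / fragLen)", {
    set.seed(4)
    for (L in c(1:50, sample(51:10000, 60))) {
        s <- strrep("A", L)
        for (fl in c(1L, 7L, 500L)) {
            fr <- fragmentScaffold(s, fragLen = fl, id = "t")
            expect_identical(length(fr), as.integer(ceiling(L / fl)))
            expect_identical(sum(Biostrings::width(fr)), L)
        }
    }
})

test_that("fragment ids are invertible", {
    p <- parseFragmentIds(c("sc1__0", "weird_name__12"))
    expect_identical(p$scaffold_id, c("sc1", "weird_name"))
    expect_identical(p$index, c(0L, 12L))
    expect_error(parseFragmentIds("nounderscore"), "not a fragment id")
})

test_that("gcContent counts called bases only", {
    expect_identical(gcContent("GCGC"), 1)
    expect_identical(gcContent("ATGCNN"), 0.5)
    expect_identical(gcContent("ATAT"), 0)

    ## constructed 1,000 bp string with exactly 407 G+C
    set.seed(5)
    s <- paste(sample(c(rep(c("G", "C"), c(204, 203)),
                        rep(c("A", "T"), c(297, 296)))), collapse = "")
    expect_equal(gcContent(s), 0.407)

    ## invariance under case change and appended Ns
    expect_identical(gcContent(tolower(s)), gcContent(s))
    expect_identical(gcContent(paste0(s, strrep("N", 50))), gcContent(s))

    expect_true(is.na(gcContent("NNNN")))
    expect_error(gcContent(""), "empty")
})

test_that("fragment FASTA write/read round-trips ids and sequences", {
    set.seed(6)
    asm <- Biostrings::DNAStringSet(
        setNames(vapply(1:5, function(i) randSeq(sample(600:3000, 1)), ""),
                 paste0("sc", 1:5)))
    fr <- fragmentAssembly(asm, 137)
    expect_identical(paste(as.character(fr), collapse = ""),
                     paste(as.character(asm), collapse = ""))
    path <- tempfile(fileext = ".fa")
    writeFragments(fr, path)
    back <- Biostrings::readDNAStringSet(path)
    expect_identical(names(back), names(fr))
    expect_identical(as.character(back), as.character(fr))

    expect_error(writeFragments(Biostrings::DNAStringSet(), path), "empty")
})
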