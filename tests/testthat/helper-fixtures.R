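## Shared fixtures and independent brute-force oracles.

## Write a FASTA file from a named character vector.
writeTestFasta <- function(seqs, path = tempfile(fileext = ".fa"),
                           wrap = NULL) {
    lines <- character(0)
    for (i in seq_along(seqs)) {
        s <- seqs[[i]]
        body <- if (is.null(wrap)) s
                else substring(s, seq(1, nchar(s), wrap),
                               pmin(seq(1, nchar(s), wrap) + wrap - 1,
                                    nchar(s)))
        lines <- c(lines, paste0(">", names(seqs)[i]), body)
    }
    writeLines(lines, path)
    path
}

## Random nucleotide string.
randSeq <- function(n, gc = 0.5) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
}

## The miniature taxonomy fixture, loaded once per test run.
fixtureDir <- file.path(tempdir(), "taxoscreen-fixture")
taxFixture <- makeTaxonomyFixture(fixtureDir)
taxTree <- loadTaxdump(taxFixture$nodes, taxFixture$merged)
twoCladeConfig <- cladeConfig(Eukaryota = 2759, Bacteria = 2)

## Independent taxdump reader + path climb (oracle for isDescendant):
## parses the dmp dialect itself and enumerates the path to root.
bruteParentMap <- function(nodesPath) {
    lines <- readLines(nodesPath)
    lines <- sub("\t\\|$", "", lines[nzchar(lines)])
    parts <- strsplit(lines, "\t|\t", fixed = TRUE)
    p <- vapply(parts, function(x) as.integer(x[2]), integer(1))
    names(p) <- vapply(parts, `[`, "", 1)
    p
}

brutePathToRoot <- function(parentMap, taxid) {
    path <- integer(0)
    cur <- taxid
    for (i in seq_len(length(parentMap) + 1L)) {
        path <- c(path, cur)
        nxt <- parentMap[[as.character(cur)]]
        if (nxt == cur) return(path)
        cur <- nxt
    }
    stop("no path to root for ", taxid)
}

## Brute-force best-hit selection: linear scan per query.
bruteBestHits <- function(hits) {
    out <- list()
    for (q in sort(unique(hits$query_id))) {
        h <- hits[hits$query_id == q, , drop = FALSE]
        best <- 1L
        for (i in seq_len(nrow(h))[-1]) {
            if (h$bitscore[i] > h$bitscore[best] ||
                (h$bitscore[i] == h$bitscore[best] &&
                 h$evalue[i] < h$evalue[best]))
                best <- i
        }
        out[[q]] <- h[best, , drop = FALSE]
    }
    res <- do.call(rbind, out)
    rownames(res) <- res$query_id
    res
}

## A hand-made best-hit table: one row per fragment id, given taxids.
fakeBestHits <- function(fragmentIds, taxids) {
    n <- length(fragmentIds)
    if (n == 0L)
        return(data.frame(query_id = character(0), taxid = integer(0),
                          evalue = numeric(0), bitscore = numeric(0),
                          stringsAsFactors = FALSE))
    data.frame(query_id = fragmentIds,
               subject_id = paste0("acc", seq_along(fragmentIds)),
               pct_identity = 95, aln_length = 400L, mismatches = 5L,
               gap_opens = 0L, q_start = 1L, q_end = 400L, s_start = 1L,
               s_end = 400L, evalue = 1e-50, bitscore = 400,
               taxid = as.integer(taxids), stringsAsFactors = FALSE,
               row.names = fragmentIds)
}

## A minimal ScreenReport from bare classification rows (for GC tests).
fakeReport <- function(ids, classifications, lengths) {
    rows <- data.frame(scaffold_id = ids, length = lengths,
                       n_fragments = pmax(1L, lengths %/% 500L),
                       n_fragments_with_hit = 0L,
                       classification = classifications,
                       stringsAsFactors = FALSE)
    summarizeAssembly(rows)
}
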