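## Tabular BLAST (outfmt 6) parsing, e-value filtering, best-hit selection.

.HIT_COLS <- c("query_id", "subject_id", "pct_identity", "aln_length",
               "mismatches", "gap_opens", "q_start", "q_end", "s_start",
               "s_end", "evalue", "bitscore", "taxid")

.emptyHits <- function() {
    out <- data.frame(query_id = character(0), subject_id = character(0),
                      pct_identity = numeric(0), aln_length = integer(0),
                      mismatches = integer(0), gap_opens = integer(0),
                      q_start = integer(0), q_end = integer(0),
                      s_start = integer(0), s_end = integer(0),
                      evalue = numeric(0), bitscore = numeric(0),
                      taxid = integer(0), stringsAsFactors = FALSE)
    out
}

#' Read alignment hits in tabular BLAST format
#'
#' Parses the standard 12-column tabular format (\code{-outfmt 6}:
#' qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore), optionally extended with a 13th \code{staxids} column.
#' The subject taxid comes either from that column
#' (\code{taxidSource = "column13"}) or from a two-column
#' subject-id-to-taxid map (\code{taxidSource = "map"}).  Multi-valued
#' \code{staxids} cells ("1224;2") take the first taxid; the event is
#' counted and reported via \code{message()}.  Hits whose taxid cannot be
#' resolved are kept with \code{taxid = NA} ("unknown") and counted — they
#' are never silently dropped or assigned to a clade downstream.
#'
#' @param path path to the tabular hit file; blank lines and \code{#}
#'   comment lines are ignored.
#' @param taxidSource \code{"column13"} (default) or \code{"map"}.
#' @param accessionMap for \code{taxidSource = "map"}: a two-column
#'   data.frame (subject id, taxid) or the path of a two-column TSV.
#' @return a data.frame with columns query_id, subject_id, pct_identity,
#'   aln_length, mismatches, gap_opens, q_start, q_end, s_start, s_end,
#'   evalue, bitscore, taxid; rows in file order.
#' @export
readBlastTab <- function(path, taxidSource = c("column13", "map"),
                         accessionMap = NULL) {
    taxidSource <- match.arg(taxidSource)
    if (!file.exists(path))
        stop("hit file not found: ", path)
    lines <- readLines(path)
    keep <- nzchar(lines) & !startsWith(lines, "#")
    lineNo <- which(keep)
    lines <- lines[keep]
    if (!length(lines))
        return(.emptyHits())
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nc <- lengths(fields)
    expected <- if (taxidSource == "column13") 13L else 12L
    bad <- which(nc != expected)
    if (length(bad))
        stop("expected ", expected, " tab-separated columns but found ",
             nc[bad[1L]], " on line ", lineNo[bad[1L]], " of ", path)
    m <- matrix(unlist(fields, use.names = FALSE), ncol = expected,
                byrow = TRUE)
    num <- function(j, what) {
        v <- suppressWarnings(as.numeric(m[, j]))
        if (anyNA(v))
            stop("unparseable ", what, " ('", m[is.na(v), j][1L],
                 "') on line ", lineNo[which(is.na(v))[1L]], " of ", path)
        v
    }
    hits <- data.frame(
        query_id = m[, 1L], subject_id = m[, 2L],
        pct_identity = num(3L, "percent identity"),
        aln_length = as.integer(num(4L, "alignment length")),
        mismatches = as.integer(num(5L, "mismatch count")),
        gap_opens = as.integer(num(6L, "gap open count")),
        q_start = as.integer(num(7L, "query start")),
        q_end = as.integer(num(8L, "query end")),
        s_start = as.integer(num(9L, "subject start")),
        s_end = as.integer(num(10L, "subject end")),
        evalue = num(11L, "e-value"),
        bitscore = num(12L, "bitscore"),
        stringsAsFactors = FALSE)
    if (any(hits$evalue < 0))
        stop("negative e-value on line ",
             lineNo[which(hits$evalue < 0)[1L]], " of ", path)
    if (taxidSource == "column13") {
        cells <- m[, 13L]
        multi <- grepl(";", cells, fixed = TRUE)
        if (any(multi))
            message(sum(multi), " hit(s) with multi-valued staxids; ",
                    "first taxid taken")
        first <- sub(";.*$", "", cells)
        taxid <- suppressWarnings(as.integer(first))
        taxid[!is.na(taxid) & taxid < 1L] <- NA_integer_
    } else {
        if (is.null(accessionMap))
            stop("taxidSource = \"map\" requires an accessionMap")
        if (is.character(accessionMap)) {
            accessionMap <- utils::read.delim(
                accessionMap, header = FALSE, colClasses = "character",
                stringsAsFactors = FALSE)
        }
        if (ncol(accessionMap) < 2L)
            stop("accessionMap must have two columns: subject id, taxid")
        taxid <- suppressWarnings(as.integer(
            accessionMap[[2L]][match(hits$subject_id, accessionMap[[1L]])]))
    }
    if (anyNA(taxid))
        message(sum(is.na(taxid)),
                " hit(s) with unresolvable subject taxid kept as unknown")
    hits$taxid <- taxid
    hits
}

#' Filter hits by e-value
#'
#' Keeps exactly the hits with \code{evalue <= cutoff} (inclusive), in input
#' order.  The conventional default cutoff in this kind of screen is 0.01;
#' tightening it to 1e-5 typically changes little because genuine
#' cross-clade hits are far below either bound.
#'
#' @param hits a hit data.frame from [readBlastTab()].
#' @param cutoff positive e-value cutoff.
#' @return the filtered data.frame.
#' @export
filterByEvalue <- function(hits, cutoff = 0.01) {
    stopifnot(is.data.frame(hits), "evalue" %in% colnames(hits))
    if (length(cutoff) != 1L || is.na(cutoff) || cutoff <= 0)
        stop("cutoff must be a single value > 0")
    hits[hits$evalue <= cutoff, , drop = FALSE]
}

#' Select the best hit per fragment
#'
#' For each query (fragment), keeps the hit with the maximal bitscore;
#' ties are broken by minimal e-value, then by first occurrence in file
#' order.  Bitscore is used for ranking because, unlike the e-value, it does
#' not depend on the database size.  The result is deterministic and
#' idempotent.
#'
#' @param hits a hit data.frame, already e-value filtered.
#' @return a data.frame with one row per distinct query_id, sorted by
#'   query_id, row names = query_id (the best-hit table).
#' @export
bestHitPerFragment <- function(hits) {
    stopifnot(is.data.frame(hits))
    if (nrow(hits) == 0L) {
        out <- if (ncol(hits)) hits else .emptyHits()
        rownames(out) <- out$query_id
        return(out)
    }
    o <- order(hits$query_id, -hits$bitscore, hits$evalue,
               seq_len(nrow(hits)), method = "radix")
    h <- hits[o, , drop = FALSE]
    best <- h[!duplicated(h$query_id), , drop = FALSE]
    rownames(best) <- best$query_id
    best
}

#' Write a best-hit table as TSV
#'
#' @param bestHits data.frame from [bestHitPerFragment()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeBestHits <- function(bestHits, path) {
    stopifnot(is.data.frame(bestHits))
    utils::write.table(bestHits, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' Read a best-hit table written by [writeBestHits()]
#'
#' @param path path to the TSV.
#' @return a best-hit data.frame with row names = query_id.
#' @export
readBestHits <- function(path) {
    out <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("query_id", "taxid", "bitscore") %in% colnames(out)))
        stop("not a best-hit table: ", path)
    out$taxid <- as.integer(out$taxid)
    rownames(out) <- out$query_id
    out
}
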