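## FASTA input, scaffold length filtering, fragmentation and GC content.

#' Read a genome assembly and apply the scaffold length filter
#'
#' Reads a (possibly line-wrapped) multi-FASTA assembly, uppercases the
#' sequences, validates the alphabet and keeps only scaffolds strictly longer
#' than \code{minLength} bp.  The count and summed length of excluded
#' scaffolds are reported via \code{message()}.
#'
#' The default \code{minLength = 2000} reflects the common practice of only
#' screening scaffolds >2 kb: shorter scaffolds carry too few fragments for a
#' percentage vote to be meaningful.  The filter is strictly greater-than.
#'
#' @param path path to a FASTA file.
#' @param minLength integer; scaffolds with \code{length <= minLength} are
#'   dropped.  Use 0 to disable the filter.
#' @return a named [Biostrings::DNAStringSet] in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "ACGTACGTAC", ">s2", "ACGT"), fa)
#' readAssembly(fa, minLength = 5)
#' @export
readAssembly <- function(path, minLength = 2000) {
    stopifnot(is.character(path), length(path) == 1L)
    if (!file.exists(path))
        stop("FASTA file not found: ", path)
    if (length(minLength) != 1L || is.na(minLength) || minLength < 0)
        stop("minLength must be a single integer >= 0")
    raw <- Biostrings::readBStringSet(path)
    if (length(raw) == 0L)
        stop("empty FASTA file: ", path)
    ids <- sub("\\s.*$", "", names(raw))
    if (any(!nzchar(ids)))
        stop("record ", which(!nzchar(ids))[1L], " has an empty id")
    dup <- unique(ids[duplicated(ids)])
    if (length(dup))
        stop("duplicate scaffold id(s): ", paste(dup, collapse = ", "))
    res <- ids[grepl("__", ids, fixed = TRUE)]
    if (length(res))
        stop("scaffold id(s) contain '__', which is reserved for fragment ",
             "ids: ", paste(res, collapse = ", "))
    seqs <- toupper(as.character(raw))
    if (any(nchar(seqs) == 0L))
        stop("record '", ids[which(nchar(seqs) == 0L)[1L]],
             "' has an empty sequence")
    ## IUPAC nucleotide codes (incl. ambiguity letters) and N only
    bad <- regexpr("[^ACGTMRWSYKVHDBN]", seqs)
    if (any(bad > 0L)) {
        i <- which(bad > 0L)[1L]
        stop("non-nucleotide character '",
             substr(seqs[i], bad[i], bad[i]), "' in record '", ids[i],
             "' at position ", bad[i])
    }
    widths <- nchar(seqs)
    keep <- widths > minLength
    if (!all(keep))
        message(sum(!keep), " scaffold(s) excluded by the length filter (<= ",
                minLength, " bp), totalling ", sum(widths[!keep]),
                " bp; ", sum(keep), " kept")
    if (!any(keep))
        stop("no scaffold longer than ", minLength, " bp in ", path)
    out <- Biostrings::DNAStringSet(seqs[keep])
    names(out) <- ids[keep]
    out
}

#' Split a scaffold into fixed-length fragments
#'
#' Tiles the scaffold with consecutive non-overlapping windows of
#' \code{fragLen} bp; the final fragment carries the remainder and may be
#' shorter.  No sequence is ever discarded: the concatenation of the
#' fragments reproduces the scaffold and the fragment count is
#' \code{ceiling(length / fragLen)}.  Fragments are named
#' \code{"<scaffold_id>__<index>"} with a 0-based index, and carry
#' \code{scaffold_id}, \code{index}, \code{start} (0-based) and \code{end}
#' (1-based inclusive, i.e. 0-based exclusive) as metadata columns.
#'
#' @param record a [Biostrings::DNAString], a length-1 named
#'   [Biostrings::DNAStringSet], or a character string.
#' @param fragLen fragment length in bp (default 500).
#' @param id scaffold id; taken from \code{names(record)} when omitted.
#' @return a [Biostrings::DNAStringSet] of fragments, in scaffold order.
#' @examples
#' frags <- fragmentScaffold(Biostrings::DNAString("ACGTACGTAC"),
#'                           fragLen = 4, id = "s1")
#' names(frags)
#' @export
fragmentScaffold <- function(record, fragLen = 500, id = NULL) {
    if (is.character(record))
        record <- Biostrings::DNAString(toupper(record))
    if (is(record, "DNAStringSet")) {
        stopifnot(length(record) == 1L)
        if (is.null(id)) id <- names(record)
        record <- record[[1L]]
    }
    if (is.null(id) || length(id) != 1L || is.na(id) || !nzchar(id))
        stop("a scaffold id is required (pass a named DNAStringSet or `id=`)")
    if (grepl("__", id, fixed = TRUE))
        stop("scaffold id '", id, "' contains the reserved separator '__'")
    fragLen <- as.integer(fragLen)
    if (length(fragLen) != 1L || is.na(fragLen) || fragLen < 1L)
        stop("fragLen must be a single integer >= 1")
    L <- length(record)
    if (L < 1L) stop("cannot fragment an empty sequence")
    starts <- seq.int(1L, L, by = fragLen)
    ends <- pmin(starts + fragLen - 1L, L)
    frags <- Biostrings::extractAt(record, IRanges::IRanges(starts, ends))
    idx <- seq_along(starts) - 1L
    names(frags) <- paste0(id, "__", idx)
    S4Vectors::mcols(frags) <- S4Vectors::DataFrame(
        scaffold_id = id, index = idx, start = starts - 1L, end = ends)
    frags
}

#' Fragment every scaffold of an assembly
#'
#' @param assembly a named [Biostrings::DNAStringSet], e.g. from
#'   [readAssembly()].
#' @inheritParams fragmentScaffold
#' @return a [Biostrings::DNAStringSet] of all fragments, scaffolds in input
#'   order, fragments in scaffold order.
#' @export
fragmentAssembly <- function(assembly, fragLen = 500) {
    stopifnot(is(assembly, "DNAStringSet"))
    if (is.null(names(assembly)) || any(!nzchar(names(assembly))))
        stop("assembly scaffolds must be named")
    pieces <- lapply(seq_along(assembly),
                     function(i) fragmentScaffold(assembly[i], fragLen))
    do.call(c, pieces)
}

#' Recover scaffold id and fragment index from fragment ids
#'
#' Inverts the \code{"<scaffold_id>__<index>"} naming scheme.
#'
#' @param fragmentIds character vector of fragment ids.
#' @return data.frame with columns \code{fragment_id}, \code{scaffold_id},
#'   \code{index}.
#' @export
parseFragmentIds <- function(fragmentIds) {
    m <- regexpr("__[0-9]+$", fragmentIds)
    if (any(m < 0L))
        stop("not a fragment id: ", fragmentIds[which(m < 0L)[1L]])
    data.frame(
        fragment_id = fragmentIds,
        scaffold_id = substr(fragmentIds, 1L, m - 1L),
        index = as.integer(substring(fragmentIds, m + 2L)),
        stringsAsFactors = FALSE)
}

#' GC content of called bases
#'
#' Computes (G + C) / (A + C + G + T), case-insensitively.  N and IUPAC
#' ambiguity codes are excluded from numerator and denominator, since the
#' compositional signal of interest rests on called bases only.  A sequence
#' with no called bases yields \code{NA}, never 0.
#'
#' @param x a character vector, [Biostrings::DNAString] or
#'   [Biostrings::DNAStringSet]; every sequence must be non-empty.
#' @return numeric vector of GC fractions in \eqn{[0, 1]} (or \code{NA}).
#' @examples
#' gcContent(c("GCGC", "ATGCNN"))
#' @export
gcContent <- function(x) {
    if (is.character(x))
        x <- Biostrings::DNAStringSet(toupper(x))
    if (is(x, "DNAString"))
        x <- Biostrings::DNAStringSet(x)
    stopifnot(is(x, "DNAStringSet"))
    if (length(x) == 0L)
        return(numeric(0))
    if (any(Biostrings::width(x) == 0L))
        stop("gcContent is undefined for an empty sequence")
    lf <- Biostrings::letterFrequency(x, letters = c("A", "C", "G", "T"))
    called <- rowSums(lf)
    out <- ifelse(called == 0L, NA_real_,
                  (lf[, "C"] + lf[, "G"]) / called)
    unname(out)
}

#' Write fragments as FASTA for an external search tool
#'
#' One record per fragment, header \code{"<scaffold_id>__<index>"}, sequences
#' wrapped at 80 columns.  Round-trips through [Biostrings::readDNAStringSet].
#'
#' @param fragments a non-empty [Biostrings::DNAStringSet] from
#'   [fragmentScaffold()] or [fragmentAssembly()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFragments <- function(fragments, path) {
    stopifnot(is(fragments, "DNAStringSet"))
    if (length(fragments) == 0L)
        stop("refusing to write an empty fragment set")
    if (is.null(names(fragments)) || any(!nzchar(names(fragments))))
        stop("fragments must be named")
    Biostrings::writeXStringSet(fragments, path, width = 80L)
    invisible(path)
}
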