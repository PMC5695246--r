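## Within-scaffold GC segmentation: recursive binary splitting on a
## GC-divergence statistic, used to localize the junctions of hybrid
## (chimeric) scaffolds.

## Default split-acceptance threshold on the scale-free score (see
## bestSplit).  Calibrated by seeded null simulation over homogeneous
## sequences (scripts/calibrate-segmentation.R): the 99.9th percentile of
## the null maximum score across sequence lengths 100 kb and 500 kb and GC
## levels 30-65%, so homogeneous sequence is essentially never split and
## the realized false-split rate sits far below a 5% budget.
.DEFAULT_SPLIT_THRESHOLD <- 18.0

#' Construct segmentation parameters
#'
#' @param minSegLen minimum segment length in bp (default 10000): splits
#'   leaving either side shorter are never considered.
#' @param threshold acceptance threshold on the scale-free split score
#'   (default calibrated by null simulation; see [bestSplit()]).
#' @param maxDepth maximum recursion depth (default 20).
#' @return a [SegParams-class].
#' @export
segParams <- function(minSegLen = 10000, threshold = .DEFAULT_SPLIT_THRESHOLD,
                      maxDepth = 20) {
    new("SegParams", minSegLen = as.integer(minSegLen),
        threshold = as.numeric(threshold), maxDepth = as.integer(maxDepth))
}

## Cumulative GC / called-base counts for fast window statistics.
.gcCumsums <- function(seq) {
    if (is(seq, "DNAStringSet")) {
        stopifnot(length(seq) == 1L)
        seq <- seq[[1L]]
    }
    s <- charToRaw(toupper(as.character(seq)))
    gc <- s == charToRaw("G") | s == charToRaw("C")
    called <- gc | s == charToRaw("A") | s == charToRaw("T")
    list(gc = cumsum(as.integer(gc)), called = cumsum(as.integer(called)),
         length = length(s))
}

## Best split of the window (from, to] of precomputed cumsums.
## position is 1-based, relative to the whole sequence: last base of the
## left part.  Returns list(splittable, position, score, D, gcLeft, gcRight).
.bestSplitRange <- function(cs, from, to, minSegLen) {
    L <- to - from + 1L
    if (L < 2L * minSegLen)
        return(list(splittable = FALSE))
    p <- (from + minSegLen - 1L):(to - minSegLen)
    g0 <- if (from > 1L) cs$gc[from - 1L] else 0L
    c0 <- if (from > 1L) cs$called[from - 1L] else 0L
    ## double arithmetic: nl * nr overflows 32-bit integers for long windows
    nl <- as.numeric(cs$called[p] - c0)
    nr <- as.numeric(cs$called[to] - cs$called[p])
    n <- as.numeric(cs$called[to] - c0)
    gTot <- cs$gc[to] - g0
    if (n == 0L || gTot == 0L || gTot == n)
        return(list(splittable = FALSE))
    gl <- (cs$gc[p] - g0) / nl
    gr <- (cs$gc[to] - cs$gc[p]) / nr
    D <- (nl * nr / n^2) * (gl - gr)^2
    D[nl == 0L | nr == 0L] <- -Inf
    i <- which.max(D)                         # first max = smallest position
    pbar <- gTot / n
    list(splittable = TRUE, position = p[i],
         score = n * D[i] / (pbar * (1 - pbar)), D = D[i],
         gcLeft = gl[i], gcRight = gr[i])
}

#' Find the best GC split point of a sequence window
#'
#' Evaluates, at every position leaving both sides at least
#' \code{minSegLen} bp, the GC divergence
#' \deqn{D(p) = \frac{n_L n_R}{n^2} (g_L - g_R)^2}
#' where \eqn{n_L, n_R} are the called-base counts and \eqn{g_L, g_R} the GC
#' fractions left and right of the split, and returns the position
#' maximizing it (exact argmax over all bases, via prefix counts; ties take
#' the smallest position).  The returned \code{score} is the scale-free
#' version \eqn{n D(p) / (\bar p (1 - \bar p))} (\eqn{\bar p} = window GC):
#' under a homogeneous window it is approximately the squared maximum of a
#' standardized Brownian bridge and hence comparable across window lengths
#' and GC levels, which lets one calibrated threshold drive the recursion of
#' [segmentScaffold()].
#'
#' @param seq a [Biostrings::DNAString], length-1 DNAStringSet, or character
#'   string.
#' @param minSegLen minimum bp on each side of the split (default 10000).
#' @return a list: \code{splittable} (FALSE when the window is shorter than
#'   \code{2 * minSegLen} or has no GC variation to speak of), and when
#'   splittable: \code{position} (1-based last base of the left part),
#'   \code{score}, \code{D}, \code{gcLeft}, \code{gcRight}.
#' @export
bestSplit <- function(seq, minSegLen = 10000) {
    cs <- .gcCumsums(seq)
    .bestSplitRange(cs, 1L, cs$length, as.integer(minSegLen))
}

#' Segment a scaffold by GC content
#'
#' Recursive binary segmentation: the best split of the current window
#' ([bestSplit()]) is accepted when its score reaches
#' \code{params@threshold}, then both sides are segmented recursively;
#' recursion also stops when a window is shorter than twice the minimum
#' segment length or at the maximum depth.  Deterministic given
#' (sequence, params).  Scaffolds shorter than \code{2 * minSegLen} yield a
#' single-segment result.  Segment bounds are reported 1-based inclusive.
#'
#' @param record a [Biostrings::DNAString], length-1 named DNAStringSet, or
#'   character string.
#' @param params a [SegParams-class].
#' @param id scaffold id; taken from \code{names(record)} when omitted.
#' @return a [Segmentation-class].
#' @export
segmentScaffold <- function(record, params = segParams(), id = NULL) {
    stopifnot(is(params, "SegParams"))
    if (is(record, "DNAStringSet")) {
        stopifnot(length(record) == 1L)
        if (is.null(id)) id <- names(record)
        record <- record[[1L]]
    }
    if (is.null(id)) id <- "scaffold"
    cs <- .gcCumsums(record)
    segGC <- function(from, to) {
        g0 <- if (from > 1L) cs$gc[from - 1L] else 0L
        c0 <- if (from > 1L) cs$called[from - 1L] else 0L
        n <- cs$called[to] - c0
        if (n == 0L) NA_real_ else (cs$gc[to] - g0) / n
    }
    segs <- list()
    recurse <- function(from, to, depth) {
        bs <- .bestSplitRange(cs, from, to, params@minSegLen)
        if (!bs$splittable) {
            segs[[length(segs) + 1L]] <<- data.frame(
                start = from, end = to, length = to - from + 1L,
                gc = segGC(from, to), score = NA_real_,
                halt = "min-length", stringsAsFactors = FALSE)
        } else if (bs$score < params@threshold) {
            segs[[length(segs) + 1L]] <<- data.frame(
                start = from, end = to, length = to - from + 1L,
                gc = segGC(from, to), score = bs$score,
                halt = "threshold", stringsAsFactors = FALSE)
        } else if (depth >= params@maxDepth) {
            segs[[length(segs) + 1L]] <<- data.frame(
                start = from, end = to, length = to - from + 1L,
                gc = segGC(from, to), score = bs$score,
                halt = "max-depth", stringsAsFactors = FALSE)
        } else {
            recurse(from, bs$position, depth + 1L)
            recurse(bs$position + 1L, to, depth + 1L)
        }
    }
    recurse(1L, cs$length, 0L)
    segments <- do.call(rbind, segs)
    segments <- segments[order(segments$start), , drop = FALSE]
    rownames(segments) <- NULL
    new("Segmentation", scaffoldId = as.character(id),
        breakpoints = as.integer(segments$end[-nrow(segments)]),
        segments = segments)
}

#' @describeIn Segmentation-class 1-based breakpoint positions (last base of
#'   each segment but the final one); empty for a homogeneous scaffold.
#' @export
setMethod("breakpoints", "Segmentation", function(x) x@breakpoints)

#' @describeIn Segmentation-class the per-segment table (start, end, length,
#'   gc, score, halt).
#' @export
setMethod("segmentTable", "Segmentation", function(x) x@segments)

setMethod("show", "Segmentation", function(object) {
    cat("Segmentation of", object@scaffoldId, "-",
        nrow(object@segments), "segment(s),",
        length(object@breakpoints), "breakpoint(s)\n")
    s <- object@segments
    for (i in seq_len(nrow(s)))
        cat(sprintf("  %9d-%9d  GC %5.1f%%  (%s)\n", s$start[i], s$end[i],
                    100 * s$gc[i], s$halt[i]))
})
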