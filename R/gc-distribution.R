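## Per-class GC-content distributions: histogram + smoothed modes.  A
## unimodal host distribution against a wide multimodal contaminant
## distribution is the classic visual check that a screen separated
## phylogenetically diverse contaminants from the target genome.

#' GC distribution of the scaffolds in one classification
#'
#' Computes per-scaffold GC content for every scaffold the report assigns to
#' \code{classLabel}, bins it into a percent histogram, smooths the counts
#' with a centered moving average and reports the modes (bin centers of
#' strict local maxima of the smoothed counts; a plateau of equal smoothed
#' counts higher than both flanks counts as one mode at its center).  Bins
#' are centered on multiples of \code{binWidth} (the first bin of the
#' default 1% grid is \eqn{[-0.5, 0.5)}), so a composition peak sitting on
#' an integer percent falls mid-bin rather than on a bin boundary.
#'
#' @param report a [ScreenReport-class].
#' @param assembly named [Biostrings::DNAStringSet] holding the scaffolds.
#' @param classLabel classification to select (e.g. a clade label).
#' @param binWidth histogram bin width in percent GC (default 1).
#' @param smoothWindow odd moving-average window in bins (default 3).
#' @return a [GCDistribution-class].
#' @export
classGCDistribution <- function(report, assembly, classLabel, binWidth = 1,
                                smoothWindow = 3) {
    stopifnot(is(report, "ScreenReport"), is(assembly, "DNAStringSet"))
    if (smoothWindow %% 2L != 1L || smoothWindow < 1L)
        stop("smoothWindow must be a positive odd number of bins")
    ids <- classifiedIds(report, classLabel)
    if (!length(ids))
        stop("no scaffolds classified as '", classLabel, "'")
    missing <- setdiff(ids, names(assembly))
    if (length(missing))
        stop("scaffold(s) absent from the assembly: ",
             paste(utils::head(missing, 3L), collapse = ", "))
    gc <- 100 * gcContent(assembly[ids])
    if (anyNA(gc))
        stop("scaffold with no called bases in class '", classLabel, "'")
    breaks <- seq(-binWidth / 2, 100 + binWidth / 2, by = binWidth)
    bin <- findInterval(gc, breaks, rightmost.closed = TRUE)
    counts <- tabulate(bin, nbins = length(breaks) - 1L)
    k <- (smoothWindow - 1L) %/% 2L
    padded <- c(rep(0, k), counts, rep(0, k))
    sm <- as.numeric(stats::filter(padded,
                                   rep(1 / smoothWindow, smoothWindow),
                                   sides = 2L))[k + seq_along(counts)]
    centers <- breaks[-length(breaks)] + binWidth / 2
    ## strict local maxima of the smoothed counts, with plateaus (runs of
    ## equal smoothed counts above both flanks) collapsed to one mode each
    r <- rle(sm)
    runEnd <- cumsum(r$lengths)
    runStart <- runEnd - r$lengths + 1L
    nbhd <- c(0, r$values, 0)
    isMax <- r$values > nbhd[seq_along(r$values)] &
             r$values > nbhd[seq_along(r$values) + 2L] & r$values > 0
    modes <- vapply(which(isMax), function(i)
        mean(centers[runStart[i]:runEnd[i]]), numeric(1L))
    new("GCDistribution", classLabel = as.character(classLabel),
        values = unname(gc), breaks = breaks, counts = as.integer(counts),
        smoothed = sm, modes = modes)
}

#' @describeIn GCDistribution-class modes in percent GC.
#' @export
setMethod("gcModes", "GCDistribution", function(x) x@modes)

#' @describeIn GCDistribution-class per-scaffold GC values in percent.
#' @export
setMethod("gcValues", "GCDistribution", function(x) x@values)

setMethod("show", "GCDistribution", function(object) {
    cat("GCDistribution for class '", object@classLabel, "': ",
        length(object@values), " scaffold(s), ",
        length(object@modes), " mode(s)",
        if (length(object@modes))
            paste0(" at ", paste(object@modes, collapse = ", "), "% GC"),
        "\n", sep = "")
})
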