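## Hybrid-scaffold flagging: re-vote the fragment best hits inside each GC
## segment of an ambiguous scaffold.  A scaffold whose segments classify to
## different clades is a hybrid — either an assembly chimera or a recent
## horizontal transfer; distinguishing the two needs evidence (coverage,
## PCR) outside this package's scope.

#' Flag hybrid scaffolds among the ambiguous ones
#'
#' For each scaffold classified \code{"ambiguous"} in the report and present
#' in \code{segmentations}, fragments are attributed to the GC segment
#' containing their midpoint and each segment is classified with the same
#' inclusive threshold rule as whole scaffolds.  A scaffold is flagged
#' \code{"hybrid"} when at least two segments classify to different clades;
#' an ambiguous scaffold with no breakpoint is \code{"mixed-unsegmented"}
#' (taxonomically mixed but compositionally uniform); anything else is
#' \code{"not-hybrid"}.
#'
#' @param report a [ScreenReport-class].
#' @param segmentations named list of [Segmentation-class] objects (names =
#'   scaffold ids), e.g. from running [segmentScaffold()] on the ambiguous
#'   scaffolds.
#' @param fragments fragment [Biostrings::DNAStringSet] for the assembly
#'   (from [fragmentAssembly()]).
#' @param bestHits best-hit table from [bestHitPerFragment()].
#' @param tree a [TaxonomyTree-class].
#' @param config a [CladeConfig-class].
#' @param threshold classification threshold in percent (default 90).
#' @return a list with \code{scaffolds} (scaffold_id, n_breakpoints,
#'   breakpoints as a comma-separated 1-based string, status,
#'   segment_classifications) and \code{segments} (scaffold_id, start, end,
#'   gc_pct, n_fragments, n_with_hit, classification).
#' @export
flagHybrids <- function(report, segmentations, fragments, bestHits, tree,
                        config, threshold = 90) {
    stopifnot(is(report, "ScreenReport"))
    ambiguous <- classifiedIds(report, "ambiguous")
    ids <- intersect(ambiguous, names(segmentations))
    mc <- S4Vectors::mcols(fragments)
    clades <- cladeLabels(config)
    scafRows <- list()
    segRows <- list()
    for (id in ids) {
        seg <- segmentations[[id]]
        stopifnot(is(seg, "Segmentation"))
        st <- segmentTable(seg)
        sel <- mc$scaffold_id == id
        fmid <- (mc$start[sel] + mc$end[sel] + 1L) %/% 2L   # 1-based midpoint
        fnames <- names(fragments)[sel]
        whichSeg <- findInterval(fmid, st$start)
        segCls <- character(nrow(st))
        for (s in seq_len(nrow(st))) {
            fn <- fnames[whichSeg == s]
            idx <- match(fn, bestHits$query_id)
            hitTax <- bestHits$taxid[idx[!is.na(idx)]]
            nHit <- sum(!is.na(idx))
            if (nHit == 0L) {
                segCls[s] <- "no_hits"
            } else {
                labs <- assignClade(tree, config, hitTax)
                denomN <- sum(labs != "unresolved")
                if (denomN == 0L) {
                    segCls[s] <- "ambiguous"
                } else {
                    pct <- 100 * vapply(clades, function(l)
                        sum(labs == l), integer(1L)) / denomN
                    q <- which(pct >= threshold)
                    segCls[s] <- if (length(q)) clades[q[1L]]
                                 else "ambiguous"
                }
            }
            segRows[[length(segRows) + 1L]] <- data.frame(
                scaffold_id = id, start = st$start[s], end = st$end[s],
                gc_pct = round(100 * st$gc[s], 2L),
                n_fragments = sum(whichSeg == s),
                n_with_hit = sum(!is.na(match(fn, bestHits$query_id))),
                classification = segCls[s], stringsAsFactors = FALSE)
        }
        cladeSegs <- unique(segCls[segCls %in% clades])
        status <- if (length(breakpoints(seg)) == 0L) "mixed-unsegmented"
                  else if (length(cladeSegs) >= 2L) "hybrid"
                  else "not-hybrid"
        scafRows[[length(scafRows) + 1L]] <- data.frame(
            scaffold_id = id, n_breakpoints = length(breakpoints(seg)),
            breakpoints = paste(breakpoints(seg), collapse = ","),
            status = status,
            segment_classifications = paste(segCls, collapse = ","),
            stringsAsFactors = FALSE)
    }
    list(
        scaffolds = if (length(scafRows)) do.call(rbind, scafRows)
                    else data.frame(scaffold_id = character(0),
                                    n_breakpoints = integer(0),
                                    breakpoints = character(0),
                                    status = character(0),
                                    segment_classifications = character(0),
                                    stringsAsFactors = FALSE),
        segments = if (length(segRows)) do.call(rbind, segRows)
                   else data.frame(scaffold_id = character(0),
                                   start = integer(0), end = integer(0),
                                   gc_pct = numeric(0),
                                   n_fragments = integer(0),
                                   n_with_hit = integer(0),
                                   classification = character(0),
                                   stringsAsFactors = FALSE))
}

#' Write a hybrid report as TSV
#'
#' Two sections are written: the per-scaffold status table and, below a
#' separating comment line, the per-segment table (1-based coordinates,
#' GC%, per-segment classification).
#'
#' @param hybrids result of [flagHybrids()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeHybridReport <- function(hybrids, path) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    wr <- function(df) {
        writeLines(paste(colnames(df), collapse = "\t"), con,
                   useBytes = TRUE)
        if (nrow(df))
            writeLines(do.call(paste, c(lapply(df, as.character),
                                        list(sep = "\t"))),
                       con, useBytes = TRUE)
    }
    writeLines("# taxoscreen hybrid-scaffold report", con, useBytes = TRUE)
    wr(hybrids$scaffolds)
    writeLines("# per-segment detail", con, useBytes = TRUE)
    wr(hybrids$segments)
    invisible(path)
}
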