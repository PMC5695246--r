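#' @import methods
NULL

#' TaxonomyTree: an NCBI-style taxonomy as parent pointers
#'
#' Holds the parent map, ranks and merged-taxid redirections loaded from
#' \code{nodes.dmp}/\code{merged.dmp}-dialect files.  Lineage lookups are
#' memoized in an internal environment; \code{\link{isDescendant}} and
#' \code{\link{assignClade}} are the query interface.
#'
#' @slot parent named integer vector, taxid (as name) to parent taxid.
#' @slot rank named character vector, taxid to rank string.
#' @slot merged named integer vector, old taxid to current taxid.
#' @slot cache environment memoizing taxid-to-root paths.
#'
#' @seealso [loadTaxdump()]
#' @export
setClass("TaxonomyTree",
    representation(parent = "integer", rank = "character",
                   merged = "integer", cache = "environment"))

setValidity("TaxonomyTree", function(object) {
    if (is.null(names(object@parent)) || anyNA(object@parent))
        return("parent map must be a named integer vector without NAs")
    if (!"1" %in% names(object@parent))
        return("taxonomy root (taxid 1) is missing")
    if (length(object@merged) &&
        any(names(object@merged) %in% names(object@parent)))
        return("merged taxids must be disjoint from node taxids")
    TRUE
})

#' CladeConfig: the target clades of a screening run
#'
#' An ordered set of labelled taxonomy subtrees (e.g. Bacteria, taxid 2;
#' Eukaryota, taxid 2759) into which fragment best hits are bucketed.  The
#' implicit buckets \code{"other"} (hit resolves to neither clade) and
#' \code{"unresolved"} (taxid unknown) always exist and their names are
#' reserved.
#'
#' @slot labels character vector of unique clade labels, in priority order.
#' @slot taxids integer vector of clade root taxids, parallel to labels.
#'
#' @seealso [cladeConfig()], [validateCladeConfig()]
#' @export
setClass("CladeConfig",
    representation(labels = "character", taxids = "integer"))

.RESERVED_LABELS <- c("other", "unresolved", "ambiguous", "no_hits")

setValidity("CladeConfig", function(object) {
    if (length(object@labels) < 1L)
        return("at least one clade is required")
    if (length(object@labels) != length(object@taxids))
        return("labels and taxids must have equal length")
    if (anyDuplicated(object@labels))
        return("clade labels must be unique")
    if (anyDuplicated(object@taxids))
        return("clade taxids must be unique")
    if (any(object@labels %in% .RESERVED_LABELS))
        return(paste0("clade labels may not use the reserved names: ",
                      paste(.RESERVED_LABELS, collapse = ", ")))
    if (any(grepl("[\t\n]", object@labels)))
        return("clade labels may not contain tabs or newlines")
    if (any(!nzchar(object@labels)))
        return("clade labels must be non-empty")
    if (anyNA(object@taxids) || any(object@taxids < 1L))
        return("clade taxids must be integers >= 1")
    TRUE
})

#' ScreenReport: per-scaffold classification of one assembly
#'
#' One row per scaffold (counts and percentages per target clade plus the
#' classification), per-classification totals, and run metadata.  Written to
#' a spreadsheet-compatible TSV by [writeReport()].
#'
#' @slot rows data.frame, one row per scaffold (see [summarizeScaffold()]).
#' @slot totals data.frame with columns classification, n_scaffolds, total_bp.
#' @slot metadata list of run parameters and package version.
#'
#' @seealso [summarizeAssembly()], [reportRows()], [reportTotals()]
#' @export
setClass("ScreenReport",
    representation(rows = "data.frame", totals = "data.frame",
                   metadata = "list"))

setValidity("ScreenReport", function(object) {
    rows <- object@rows
    need <- c("scaffold_id", "length", "n_fragments",
              "n_fragments_with_hit", "classification")
    if (!all(need %in% colnames(rows)))
        return(paste0("rows must contain the columns: ",
                      paste(need, collapse = ", ")))
    if (anyDuplicated(rows$scaffold_id))
        return("duplicate scaffold ids in report rows")
    tot <- object@totals
    if (!all(c("classification", "n_scaffolds", "total_bp") %in% colnames(tot)))
        return("totals must have classification, n_scaffolds, total_bp")
    ## totals must equal the column sums of the rows
    for (i in seq_len(nrow(tot))) {
        sel <- rows$classification == tot$classification[i]
        if (sum(sel) != tot$n_scaffolds[i] ||
            sum(rows$length[sel]) != tot$total_bp[i])
            return("totals do not match row sums")
    }
    TRUE
})

#' SegParams: tuning parameters for GC segmentation
#'
#' @slot minSegLen integer, minimum segment length in bp (default 10000).
#' @slot threshold numeric, acceptance threshold on the scale-free split
#'   score (see [bestSplit()]); the default is calibrated by null simulation
#'   so that homogeneous sequences are essentially never split.
#' @slot maxDepth integer, maximum recursion depth.
#'
#' @seealso [segParams()], [segmentScaffold()]
#' @export
setClass("SegParams",
    representation(minSegLen = "integer", threshold = "numeric",
                   maxDepth = "integer"))

setValidity("SegParams", function(object) {
    if (length(object@minSegLen) != 1L || is.na(object@minSegLen) ||
        object@minSegLen < 2L)
        return("minSegLen must be a single integer >= 2")
    if (length(object@threshold) != 1L || is.na(object@threshold) ||
        object@threshold <= 0)
        return("threshold must be a single positive number")
    if (length(object@maxDepth) != 1L || is.na(object@maxDepth) ||
        object@maxDepth < 1L)
        return("maxDepth must be a single integer >= 1")
    TRUE
})

#' Segmentation: GC-homogeneous segments of one scaffold
#'
#' Result of recursive binary GC segmentation.  Segment bounds are 1-based
#' inclusive (the human-facing convention); breakpoints are the last base of
#' every segment but the final one.
#'
#' @slot scaffoldId scaffold identifier.
#' @slot breakpoints integer vector of 1-based breakpoint positions,
#'   strictly increasing (empty for a homogeneous scaffold).
#' @slot segments data.frame with columns start, end, length, gc, score
#'   (best internal split score, NA when the segment is too short to split)
#'   and halt (why recursion stopped: "threshold", "min-length", "max-depth").
#'
#' @seealso [segmentScaffold()], [breakpoints()]
#' @export
setClass("Segmentation",
    representation(scaffoldId = "character", breakpoints = "integer",
                   segments = "data.frame"))

setValidity("Segmentation", function(object) {
    seg <- object@segments
    if (!all(c("start", "end", "gc", "halt") %in% colnames(seg)))
        return("segments must have start, end, gc, halt columns")
    if (nrow(seg) == 0L)
        return("at least one segment is required")
    if (is.unsorted(object@breakpoints, strictly = TRUE))
        return("breakpoints must be strictly increasing")
    if (seg$start[1L] != 1L)
        return("segments must start at base 1")
    if (nrow(seg) > 1L &&
        !all(seg$start[-1L] == seg$end[-nrow(seg)] + 1L))
        return("segments must tile the scaffold without gaps or overlaps")
    if (!identical(as.integer(object@breakpoints),
                   as.integer(seg$end[-nrow(seg)])))
        return("breakpoints must equal the ends of all but the last segment")
    TRUE
})

#' GCDistribution: per-class distribution of scaffold GC content
#'
#' GC values (percent) of all scaffolds in one classification, their
#' histogram, and the modes (bin centers of strict local maxima after
#' moving-average smoothing).
#'
#' @slot classLabel the classification the distribution describes.
#' @slot values numeric, per-scaffold GC in percent.
#' @slot breaks histogram bin breaks in percent.
#' @slot counts integer histogram counts (sum = number of scaffolds).
#' @slot smoothed moving-average smoothed counts.
#' @slot modes numeric, modes in percent GC.
#'
#' @seealso [classGCDistribution()]
#' @export
setClass("GCDistribution",
    representation(classLabel = "character", values = "numeric",
                   breaks = "numeric", counts = "integer",
                   smoothed = "numeric", modes = "numeric"))

setValidity("GCDistribution", function(object) {
    if (sum(object@counts) != length(object@values))
        return("histogram counts must sum to the number of scaffolds")
    if (length(object@counts) != length(object@breaks) - 1L)
        return("counts must have one entry per histogram bin")
    TRUE
})
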