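## Per-scaffold aggregation of fragment best hits, the >=90% decision rule,
## and the tab-separated report.

#' Summarize one scaffold's fragment best hits
#'
#' Counts, per target clade, how many of the scaffold's fragments have their
#' best hit inside that clade; converts the counts to percentages; and
#' classifies the scaffold with an inclusive threshold rule: the scaffold is
#' assigned to the first clade whose percentage is \code{>= threshold}
#' (default 90), \code{"ambiguous"} when no clade reaches the threshold, and
#' \code{"no_hits"} when no fragment has a surviving hit.  With disjoint
#' clades and a threshold above 50 at most one clade can qualify, so the
#' classification is unique.
#'
#' The percentage denominator is, by default, the fragments whose best hit
#' resolved anywhere in the taxonomy (configured clades plus \code{"other"});
#' \code{"unresolved"} hits are excluded from the denominator but always
#' reported alongside.  Set \code{denominator = "clades"} to restrict the
#' denominator to hits inside the configured clades only.
#'
#' @param fragments fragments of a single scaffold, from
#'   [fragmentScaffold()].
#' @param bestHits best-hit table from [bestHitPerFragment()].
#' @param tree a [TaxonomyTree-class].
#' @param config a [CladeConfig-class] (validated against \code{tree}).
#' @param threshold classification threshold in percent, in (50, 100].
#' @param denominator \code{"resolved"} (default) or \code{"clades"}.
#' @param minInformativeHits classify only scaffolds with at least this many
#'   denominator hits (default 1); below it the scaffold is "ambiguous".
#' @return a one-row data.frame: scaffold_id, length, n_fragments,
#'   n_fragments_with_hit, then per clade \code{n_<label>} and
#'   \code{pct_<label>}, then n_other, n_unresolved, classification.
#' @export
summarizeScaffold <- function(fragments, bestHits, tree, config,
                              threshold = 90,
                              denominator = c("resolved", "clades"),
                              minInformativeHits = 1L) {
    denominator <- match.arg(denominator)
    stopifnot(is(tree, "TaxonomyTree"), is(config, "CladeConfig"),
              is.data.frame(bestHits))
    if (length(threshold) != 1L || is.na(threshold) ||
        threshold <= 50 || threshold > 100)
        stop("threshold must lie in (50, 100] percent")
    mc <- S4Vectors::mcols(fragments)
    if (is.null(mc) || !all(c("scaffold_id", "end") %in% colnames(mc)))
        stop("fragments must carry fragmentScaffold() metadata columns")
    sid <- unique(mc$scaffold_id)
    if (length(sid) != 1L)
        stop("fragments from more than one scaffold: ",
             paste(sid, collapse = ", "))
    scafLen <- max(mc$end)
    nFrag <- length(fragments)
    idx <- match(names(fragments), bestHits$query_id)
    nHit <- sum(!is.na(idx))
    labs <- if (nHit > 0L)
        assignClade(tree, config, bestHits$taxid[idx[!is.na(idx)]])
    else character(0)
    clades <- cladeLabels(config)
    counts <- vapply(c(clades, "other", "unresolved"),
                     function(l) sum(labs == l), integer(1L))
    denomN <- if (denominator == "resolved")
        nHit - counts[["unresolved"]]
    else
        sum(counts[clades])
    pct <- if (denomN > 0L)
        100 * counts[c(clades, "other")] / denomN
    else
        stats::setNames(rep(NA_real_, length(clades) + 1L),
                        c(clades, "other"))
    classification <- if (nFrag > 0L && nHit == 0L) {
        "no_hits"
    } else if (denomN < max(1L, as.integer(minInformativeHits))) {
        "ambiguous"
    } else {
        q <- which(pct[clades] >= threshold)
        if (length(q)) clades[q[1L]] else "ambiguous"
    }
    row <- data.frame(scaffold_id = sid, length = scafLen,
                      n_fragments = nFrag, n_fragments_with_hit = nHit,
                      stringsAsFactors = FALSE, check.names = FALSE)
    for (l in clades) {
        row[[paste0("n_", l)]] <- counts[[l]]
        row[[paste0("pct_", l)]] <- unname(pct[[l]])
    }
    row[["n_other"]] <- counts[["other"]]
    row[["n_unresolved"]] <- counts[["unresolved"]]
    row[["classification"]] <- classification
    row
}

#' Summarize all scaffolds of an assembly into a report
#'
#' Binds per-scaffold summaries, sorts by scaffold id, and computes
#' per-classification totals (scaffold count and summed bp) — the shape in
#' which screening results are usually quoted ("N scaffolds, M Mbp
#' classified as bacterial"); scaffolds without hits are one of the
#' classifications and hence totalled separately.
#'
#' @param summaries a list of one-row data.frames from
#'   [summarizeScaffold()], or one row-bound data.frame.
#' @param parameters optional named list of run parameters recorded in the
#'   report metadata.
#' @return a [ScreenReport-class].
#' @export
summarizeAssembly <- function(summaries, parameters = list()) {
    rows <- if (is.data.frame(summaries)) summaries
            else do.call(rbind, summaries)
    if (is.null(rows) || nrow(rows) == 0L)
        stop("no scaffold summaries supplied")
    dup <- unique(rows$scaffold_id[duplicated(rows$scaffold_id)])
    if (length(dup))
        stop("duplicate scaffold id(s): ", paste(dup, collapse = ", "))
    rows <- rows[order(rows$scaffold_id, method = "radix"), , drop = FALSE]
    rownames(rows) <- NULL
    cls <- sort(unique(rows$classification))
    totals <- data.frame(
        classification = cls,
        n_scaffolds = vapply(cls, function(c)
            sum(rows$classification == c), integer(1L)),
        total_bp = vapply(cls, function(c)
            sum(rows$length[rows$classification == c]), numeric(1L)),
        stringsAsFactors = FALSE)
    rownames(totals) <- NULL
    new("ScreenReport", rows = rows, totals = totals,
        metadata = list(
            package = "taxoscreen",
            version = as.character(utils::packageVersion("taxoscreen")),
            parameters = parameters))
}

#' @describeIn ScreenReport-class the per-scaffold rows.
#' @export
setMethod("reportRows", "ScreenReport", function(x) x@rows)

#' @describeIn ScreenReport-class per-classification totals.
#' @export
setMethod("reportTotals", "ScreenReport", function(x) x@totals)

#' @describeIn ScreenReport-class run metadata.
#' @export
setMethod("reportMetadata", "ScreenReport", function(x) x@metadata)

setMethod("show", "ScreenReport", function(object) {
    cat("ScreenReport:", nrow(object@rows), "scaffold(s)\n")
    t <- object@totals
    for (i in seq_len(nrow(t)))
        cat(sprintf("  %-12s %5d scaffold(s) %12.0f bp\n",
                    t$classification[i], t$n_scaffolds[i], t$total_bp[i]))
})

#' Scaffold ids of a given classification
#'
#' Convenience for building keep/remove lists without editing the input
#' FASTA (destructive editing is deliberately left to the user).
#'
#' @param report a [ScreenReport-class].
#' @param classification one or more classification labels.
#' @return character vector of scaffold ids.
#' @export
classifiedIds <- function(report, classification) {
    rows <- reportRows(report)
    rows$scaffold_id[rows$classification %in% classification]
}

#' Write a screening report as tab-separated text
#'
#' Leading \code{#} comment lines carry the run metadata and totals; then a
#' header row and one row per scaffold.  UTF-8, LF line endings, "." decimal
#' separator, percentages with 2 decimals — readable by any spreadsheet
#' program and by [readReport()].
#'
#' @param report a [ScreenReport-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeReport <- function(report, path) {
    stopifnot(is(report, "ScreenReport"))
    rows <- reportRows(report)
    if (any(grepl("[\t\n]", rows$scaffold_id)))
        stop("scaffold ids may not contain tabs or newlines")
    md <- reportMetadata(report)
    hdr <- c(sprintf("# %s scaffold classification report (version %s)",
                     md$package, md$version))
    for (p in names(md$parameters))
        hdr <- c(hdr, sprintf("# parameter %s: %s", p,
                              paste(md$parameters[[p]], collapse = ",")))
    t <- reportTotals(report)
    for (i in seq_len(nrow(t)))
        hdr <- c(hdr, sprintf("# total %s: %d scaffolds, %.0f bp",
                              t$classification[i], t$n_scaffolds[i],
                              t$total_bp[i]))
    fmt <- rows
    for (col in grep("^pct_", colnames(fmt), value = TRUE))
        fmt[[col]] <- ifelse(is.na(rows[[col]]), "NA",
                             sprintf("%.2f", rows[[col]]))
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(hdr, con, sep = "\n", useBytes = TRUE)
    writeLines(paste(colnames(fmt), collapse = "\t"), con, sep = "\n",
               useBytes = TRUE)
    body <- do.call(paste, c(lapply(fmt, as.character), list(sep = "\t")))
    if (length(body))
        writeLines(body, con, sep = "\n", useBytes = TRUE)
    invisible(path)
}

#' Read back a report written by [writeReport()]
#'
#' @param path path to the TSV report.
#' @return a data.frame of the per-scaffold rows; the leading comment lines
#'   are attached as \code{attr(, "comments")}.
#' @export
readReport <- function(path) {
    lines <- readLines(path)
    comments <- lines[startsWith(lines, "#")]
    out <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                             stringsAsFactors = FALSE, check.names = FALSE)
    if (!"scaffold_id" %in% colnames(out))
        stop("not a taxoscreen report: ", path)
    attr(out, "comments") <- comments
    out
}

#' Run the full classification pipeline on one assembly
#'
#' Convenience wrapper: fragments every scaffold, filters the supplied hits
#' by e-value, selects the best hit per fragment, summarizes every scaffold
#' and assembles the report.  The alignment search itself is external: any
#' tool emitting standard 12/13-column tabular output can produce
#' \code{hits}.
#'
#' @param assembly named [Biostrings::DNAStringSet] (e.g. [readAssembly()]).
#' @param hits hit data.frame from [readBlastTab()], for the fragments of
#'   \code{assembly} at this \code{fragLen}.
#' @param tree a [TaxonomyTree-class].
#' @param config a [CladeConfig-class].
#' @param fragLen fragment length in bp (default 500).
#' @param evalueCutoff e-value cutoff (default 0.01).
#' @param threshold classification threshold in percent (default 90).
#' @param denominator percentage denominator, see [summarizeScaffold()].
#' @param minInformativeHits see [summarizeScaffold()].
#' @return a list with elements \code{report} ([ScreenReport-class]),
#'   \code{fragments} and \code{bestHits}.
#' @export
screenAssembly <- function(assembly, hits, tree, config, fragLen = 500,
                           evalueCutoff = 0.01, threshold = 90,
                           denominator = c("resolved", "clades"),
                           minInformativeHits = 1L) {
    denominator <- match.arg(denominator)
    validateCladeConfig(tree, config)
    fragments <- fragmentAssembly(assembly, fragLen)
    best <- bestHitPerFragment(filterByEvalue(hits, evalueCutoff))
    mc <- S4Vectors::mcols(fragments)
    summaries <- lapply(names(assembly), function(id) {
        summarizeScaffold(fragments[mc$scaffold_id == id], best, tree,
                          config, threshold = threshold,
                          denominator = denominator,
                          minInformativeHits = minInformativeHits)
    })
    report <- summarizeAssembly(summaries, parameters = list(
        frag_len = fragLen, evalue_cutoff = evalueCutoff,
        threshold = threshold, denominator = denominator,
        clades = paste0(cladeLabels(config), ":", cladeTaxids(config))))
    list(report = report, fragments = fragments, bestHits = best)
}
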