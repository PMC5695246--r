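## NCBI-taxdump loading and clade-membership queries.

.parseDmp <- function(path) {
    if (!file.exists(path))
        stop("taxonomy dump file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    lines <- sub("\t\\|$", "", lines)
    strsplit(lines, "\t|\t", fixed = TRUE)
}

#' Load an NCBI-style taxonomy dump
#'
#' Reads \code{nodes.dmp} (fields separated by \code{"\t|\t"}, rows
#' terminated by \code{"\t|"}; columns taxid, parent taxid, rank, ...) and
#' optionally \code{merged.dmp} (old taxid, new taxid).  The whole tree is
#' validated on load: every node must reach root 1, a node whose parent is
#' absent or that takes part in a cycle is a hard error, and merged taxids
#' must be disjoint from the node table.
#'
#' @param nodesPath path to a nodes.dmp-dialect file.
#' @param mergedPath optional path to a merged.dmp-dialect file.
#' @return a [TaxonomyTree-class].
#' @export
loadTaxdump <- function(nodesPath, mergedPath = NULL) {
    rows <- .parseDmp(nodesPath)
    if (!length(rows))
        stop("empty nodes file: ", nodesPath)
    nf <- lengths(rows)
    if (any(nf < 2L))
        stop("malformed nodes row ", which(nf < 2L)[1L], " in ", nodesPath)
    tx <- suppressWarnings(as.integer(vapply(rows, `[`, "", 1L)))
    px <- suppressWarnings(as.integer(vapply(rows, `[`, "", 2L)))
    if (anyNA(tx) || anyNA(px))
        stop("non-integer taxid in nodes row ",
             which(is.na(tx) | is.na(px))[1L], " of ", nodesPath)
    rank <- vapply(rows, function(r) if (length(r) >= 3L) r[3L]
                   else NA_character_, "")
    if (anyDuplicated(tx))
        stop("duplicate taxid ", tx[duplicated(tx)][1L], " in ", nodesPath)
    parent <- px
    names(parent) <- as.character(tx)
    names(rank) <- as.character(tx)
    if (!"1" %in% names(parent))
        stop("taxonomy root (taxid 1) missing from ", nodesPath)
    missingParent <- !(as.character(px) %in% names(parent))
    if (any(missingParent)) {
        i <- which(missingParent)[1L]
        stop("taxid ", tx[i], " has absent parent ", px[i])
    }
    selfp <- tx[px == tx & tx != 1L]
    if (length(selfp))
        stop("taxid ", selfp[1L], " is its own parent (only root 1 may be)")
    ## cycle check by climbing with a colouring memo
    state <- integer(length(tx))               # 0 new, 1 on path, 2 done
    names(state) <- names(parent)
    for (t in names(parent)) {
        if (state[[t]] != 0L) next
        path <- character(0)
        cur <- t
        repeat {
            s <- state[[cur]]
            if (s == 2L) break
            if (s == 1L)
                stop("cycle in taxonomy involving taxid ", cur)
            state[[cur]] <- 1L
            path <- c(path, cur)
            p <- as.character(parent[[cur]])
            if (p == cur) break                 # reached root
            cur <- p
        }
        state[path] <- 2L
    }
    merged <- integer(0)
    if (!is.null(mergedPath)) {
        mr <- .parseDmp(mergedPath)
        if (length(mr)) {
            old <- suppressWarnings(as.integer(vapply(mr, `[`, "", 1L)))
            new <- suppressWarnings(as.integer(vapply(mr, `[`, "", 2L)))
            if (anyNA(old) || anyNA(new))
                stop("non-integer taxid in merged row ",
                     which(is.na(old) | is.na(new))[1L], " of ", mergedPath)
            merged <- new
            names(merged) <- as.character(old)
            clash <- intersect(names(merged), names(parent))
            if (length(clash))
                stop("merged taxid ", clash[1L],
                     " is also present in the node table")
            dangling <- !(as.character(new) %in% names(parent))
            if (any(dangling))
                stop("merged taxid ", old[which(dangling)[1L]],
                     " points at absent taxid ", new[which(dangling)[1L]])
        }
    }
    new("TaxonomyTree", parent = parent, rank = rank, merged = merged,
        cache = new.env(parent = emptyenv()))
}

#' Resolve taxids through merged-taxid redirections
#'
#' @param tree a [TaxonomyTree-class].
#' @param taxid integer vector of taxids (NA allowed).
#' @return integer vector: the current taxid for each input, or \code{NA}
#'   when the taxid is unknown to the tree ("unresolved").
#' @export
resolveTaxid <- function(tree, taxid) {
    stopifnot(is(tree, "TaxonomyTree"))
    t <- as.integer(taxid)
    key <- as.character(t)
    if (length(tree@merged)) {
        m <- match(key, names(tree@merged))
        hit <- !is.na(m)
        t[hit] <- tree@merged[m[hit]]
        key <- as.character(t)
    }
    t[!(key %in% names(tree@parent))] <- NA_integer_
    t
}

## Path from a (resolved, existing) taxid up to root, inclusive; memoized.
.taxPath <- function(tree, taxid, useCache = TRUE) {
    key <- as.character(taxid)
    if (useCache) {
        v <- tree@cache[[key]]
        if (!is.null(v)) return(v)
    }
    parent <- tree@parent
    out <- integer(0)
    cur <- taxid
    repeat {
        out <- c(out, cur)
        nxt <- parent[[as.character(cur)]]
        if (nxt == cur) break
        cur <- nxt
    }
    if (useCache) assign(key, out, envir = tree@cache)
    out
}

#' Is a taxid a descendant of an ancestor taxid?
#'
#' True iff \code{ancestor} lies on the path from \code{taxid} to the root,
#' including \code{taxid} itself (every taxon is its own descendant).
#' Unknown taxids yield \code{NA} ("unresolved"), never \code{FALSE}.
#'
#' @param tree a [TaxonomyTree-class].
#' @param taxid integer vector of query taxids (merged ids are redirected).
#' @param ancestor a single taxid; must be resolvable.
#' @return logical vector, \code{NA} where taxid is unresolved.
#' @export
#' @aliases isDescendant,TaxonomyTree-method
setMethod("isDescendant", "TaxonomyTree", function(tree, taxid, ancestor) {
    stopifnot(length(ancestor) == 1L)
    anc <- resolveTaxid(tree, ancestor)
    if (is.na(anc))
        stop("ancestor taxid ", ancestor, " is not in the taxonomy")
    r <- resolveTaxid(tree, taxid)
    vapply(r, function(t) {
        if (is.na(t)) return(NA)
        anc %in% .taxPath(tree, t)
    }, logical(1L))
})

#' Construct a clade configuration
#'
#' @param ... named integers, e.g.
#'   \code{cladeConfig(Eukaryota = 2759, Bacteria = 2)}.  Order is the
#'   priority order used by [assignClade()].
#' @return a [CladeConfig-class].
#' @export
cladeConfig <- function(...) {
    v <- c(...)
    if (length(v) == 0L)
        stop("at least one clade is required")
    if (is.null(names(v)) || any(!nzchar(names(v))))
        stop("clades must be named, e.g. cladeConfig(Eukaryota = 2759)")
    new("CladeConfig", labels = names(v), taxids = as.integer(v))
}

#' Validate a clade configuration against a taxonomy
#'
#' Checks that every clade taxid resolves in the tree and that no configured
#' clade is an ancestor of another.  Overlapping clades would make the
#' per-scaffold percentages ambiguous, so overlap is rejected by default;
#' pass \code{allowOverlap = TRUE} to override deliberately.
#'
#' @param tree a [TaxonomyTree-class].
#' @param config a [CladeConfig-class].
#' @param allowOverlap logical; permit nested clades.
#' @return \code{config}, invisibly, on success.
#' @export
validateCladeConfig <- function(tree, config, allowOverlap = FALSE) {
    stopifnot(is(tree, "TaxonomyTree"), is(config, "CladeConfig"))
    r <- resolveTaxid(tree, config@taxids)
    if (anyNA(r))
        stop("clade taxid ", config@taxids[which(is.na(r))[1L]],
             " ('", config@labels[which(is.na(r))[1L]],
             "') is not in the taxonomy")
    if (!allowOverlap && length(r) > 1L) {
        for (i in seq_along(r)) for (j in seq_along(r)) {
            if (i != j && isTRUE(isDescendant(tree, r[i], r[j])))
                stop("clade '", config@labels[i], "' lies inside clade '",
                     config@labels[j],
                     "'; overlapping clades make percentages ambiguous ",
                     "(set allowOverlap = TRUE to override)")
        }
    }
    invisible(config)
}

#' Assign taxids to target clades
#'
#' Returns, for every taxid, the label of the first configured clade (in
#' config order) of which it is a descendant; \code{"other"} when it
#' resolves in the tree but belongs to no configured clade; and
#' \code{"unresolved"} when the taxid is unknown (NA, deleted, or absent).
#'
#' @param tree a [TaxonomyTree-class].
#' @param config a [CladeConfig-class].
#' @param taxid integer vector.
#' @return character vector of labels.
#' @export
#' @aliases assignClade,TaxonomyTree,CladeConfig-method
setMethod("assignClade", signature("TaxonomyTree", "CladeConfig"),
          function(tree, config, taxid) {
    r <- resolveTaxid(tree, taxid)
    u <- unique(r)
    lab <- vapply(u, function(t) {
        if (is.na(t)) return("unresolved")
        path <- .taxPath(tree, t)
        pos <- match(config@taxids, path)
        i <- which(!is.na(pos))
        if (length(i)) config@labels[i[1L]] else "other"
    }, "")
    lab[match(r, u)]
})

#' @describeIn CladeConfig-class clade labels in priority order.
#' @export
setMethod("cladeLabels", "CladeConfig", function(x) x@labels)

#' @describeIn CladeConfig-class clade root taxids.
#' @export
setMethod("cladeTaxids", "CladeConfig", function(x) x@taxids)

setMethod("show", "TaxonomyTree", function(object) {
    cat("TaxonomyTree with", length(object@parent), "nodes,",
        length(object@merged), "merged taxids\n")
})

setMethod("show", "CladeConfig", function(object) {
    cat("CladeConfig with", length(object@labels), "target clade(s):\n")
    for (i in seq_along(object@labels))
        cat("  ", object@labels[i], " (taxid ", object@taxids[i], ")\n",
            sep = "")
})
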