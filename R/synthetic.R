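## Seeded synthetic fixtures: a miniature NCBI-style taxonomy, planted
## assemblies with known composition, and mock tabular hit files.  Together
## they make the whole pipeline testable offline, with the planting manifest
## as ground truth.  GC emission is i.i.d. per base — enough to exercise
## every pipeline decision; oligonucleotide realism is out of scope.

#' Miniature taxonomy fixture in taxdump dialect
#'
#' Writes a ~18-node nodes.dmp/merged.dmp pair containing root (1),
#' Bacteria (2) and Eukaryota (2759); under Eukaryota the brown algae
#' (Phaeophyceae, 2870) and diatoms (Bacillariophyta, 2836) with genus
#' leaves; under Bacteria several phyla with genus leaves typical of marine
#' biofilms (Haliea, Methylophaga, Lewinella, Marinoscillum,
#' Pseudonocardia, Rhodobacteraceae).  merged.dmp maps the retired taxid
#' 666 to Bacteria (2).
#'
#' @param dir directory to write \code{nodes.dmp} and \code{merged.dmp} in.
#' @return a list: \code{nodes}, \code{merged} (file paths) and
#'   \code{leaves}, a named list of leaf taxids per major clade
#'   (\code{Bacteria}, \code{Phaeophyceae}, \code{Bacillariophyta}).
#' @export
makeTaxonomyFixture <- function(dir = tempfile("taxdump")) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    nodes <- rbind(
        c(1L,      1L,      "no rank"),
        c(2L,      1L,      "superkingdom"),   # Bacteria
        c(2759L,   1L,      "superkingdom"),   # Eukaryota
        c(1224L,   2L,      "phylum"),         # Proteobacteria
        c(1236L,   1224L,   "class"),          # Gammaproteobacteria
        c(28211L,  1224L,   "class"),          # Alphaproteobacteria
        c(976L,    2L,      "phylum"),         # Bacteroidetes
        c(201174L, 2L,      "phylum"),         # Actinobacteria
        c(109578L, 1236L,   "genus"),          # Haliea
        c(40222L,  1236L,   "genus"),          # Methylophaga
        c(31989L,  28211L,  "family"),         # Rhodobacteraceae
        c(106902L, 976L,    "genus"),          # Lewinella
        c(643701L, 976L,    "genus"),          # Marinoscillum
        c(1847L,   201174L, "genus"),          # Pseudonocardia
        c(2836L,   2759L,   "class"),          # Bacillariophyta (diatoms)
        c(2870L,   2759L,   "class"),          # Phaeophyceae (brown algae)
        c(2880L,   2870L,   "genus"),          # Ectocarpus
        c(88149L,  2870L,   "genus"),          # Saccharina
        c(35127L,  2836L,   "genus"))          # Thalassiosira
    nodesPath <- file.path(dir, "nodes.dmp")
    writeLines(paste0(nodes[, 1L], "\t|\t", nodes[, 2L], "\t|\t",
                      nodes[, 3L], "\t|"), nodesPath)
    mergedPath <- file.path(dir, "merged.dmp")
    writeLines("666\t|\t2\t|", mergedPath)
    list(nodes = nodesPath, merged = mergedPath,
         leaves = list(
             Bacteria = c(109578L, 40222L, 31989L, 106902L, 643701L, 1847L),
             Phaeophyceae = c(2880L, 88149L),
             Bacillariophyta = 35127L))
}

#' Default planting manifest for the demo assembly
#'
#' The demo study conditions: 50 pure host scaffolds (50 kb, 49% GC — the
#' narrow unimodal host composition typical of a brown algal genome), 40
#' bacterial contaminant scaffolds (40 kb) across the four GC levels 30, 38,
#' 53 and 64% (phylogenetically diverse biofilm bacteria), and 10 hybrid
#' scaffolds (40 kb bacterial 5' part + 40 kb host part, junction at
#' 40,000 bp).  Lengths are chosen so each scaffold carries enough 500 bp
#' fragments for a 90% vote to be statistically meaningful.
#'
#' @param nHost,nContaminant,nHybrid scaffold counts per class.
#' @param hostGC host GC fraction (default 0.49).
#' @param contaminantGC GC fractions cycled over contaminant scaffolds.
#' @param hostLength,contaminantLength scaffold lengths in bp.
#' @param hybridSegLengths lengths in bp of the bacterial and host part of
#'   each hybrid scaffold.
#' @return the planting manifest: a data.frame with one row per scaffold
#'   (scaffold_id, class, clade, length, gc1, len1, gc2, len2, junction).
#'   \code{clade} is the true clade of pure scaffolds; hybrids are Bacteria
#'   up to \code{junction}, host (Eukaryota) after it.
#' @export
demoManifest <- function(nHost = 50, nContaminant = 40, nHybrid = 10,
                         hostGC = 0.49,
                         contaminantGC = c(0.30, 0.38, 0.53, 0.64),
                         hostLength = 50000, contaminantLength = 40000,
                         hybridSegLengths = c(40000, 40000)) {
    stopifnot(nHost >= 0, nContaminant >= 0, nHybrid >= 0,
              length(hybridSegLengths) == 2L)
    rows <- list()
    add <- function(class, clade, len1, gc1, len2 = NA_real_,
                    gc2 = NA_real_) {
        rows[[length(rows) + 1L]] <<- data.frame(
            class = class, clade = clade,
            length = len1 + ifelse(is.na(len2), 0, len2),
            gc1 = gc1, len1 = len1, gc2 = gc2, len2 = len2,
            junction = ifelse(is.na(len2), NA_real_, len1),
            stringsAsFactors = FALSE)
    }
    for (i in seq_len(nHost))
        add("host", "Eukaryota", hostLength, hostGC)
    for (i in seq_len(nContaminant))
        add("contaminant", "Bacteria", contaminantLength,
            contaminantGC[(i - 1L) %% length(contaminantGC) + 1L])
    for (i in seq_len(nHybrid))
        add("hybrid", "hybrid", hybridSegLengths[1L],
            contaminantGC[(i - 1L) %% length(contaminantGC) + 1L],
            hybridSegLengths[2L], hostGC)
    manifest <- do.call(rbind, rows)
    manifest <- cbind(
        scaffold_id = sprintf("scaffold%04d", seq_len(nrow(manifest))),
        manifest, stringsAsFactors = FALSE)
    manifest
}

.randSeq <- function(n, gc) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
}

#' Generate a planted synthetic assembly
#'
#' Emits each scaffold base-by-base at its planted GC level(s) (binomial
#' per-base emission).  Deterministic under \code{seed}: the same seed
#' yields a byte-identical FASTA.  The manifest is written alongside as
#' JSON.
#'
#' @param manifest a planting manifest, e.g. [demoManifest()].
#' @param seed integer RNG seed.
#' @param dir output directory (created if needed); when \code{NULL},
#'   nothing is written and only the in-memory assembly is returned.
#' @return a list: \code{assembly} (named [Biostrings::DNAStringSet]),
#'   \code{manifest}, and when written, \code{fasta} and \code{manifestPath}.
#' @export
makeAssembly <- function(manifest, seed, dir = NULL) {
    stopifnot(is.data.frame(manifest), all(c("scaffold_id", "len1", "gc1")
                                           %in% colnames(manifest)))
    set.seed(as.integer(seed))
    seqs <- vapply(seq_len(nrow(manifest)), function(i) {
        s <- .randSeq(manifest$len1[i], manifest$gc1[i])
        if (!is.na(manifest$len2[i]) && manifest$len2[i] > 0)
            s <- paste0(s, .randSeq(manifest$len2[i], manifest$gc2[i]))
        s
    }, "")
    assembly <- Biostrings::DNAStringSet(seqs)
    names(assembly) <- manifest$scaffold_id
    out <- list(assembly = assembly, manifest = manifest)
    if (!is.null(dir)) {
        dir.create(dir, showWarnings = FALSE, recursive = TRUE)
        out$fasta <- file.path(dir, "assembly.fasta")
        Biostrings::writeXStringSet(assembly, out$fasta, width = 80L)
        out$manifestPath <- file.path(dir, "manifest.json")
        jsonlite::write_json(manifest, out$manifestPath,
                             dataframe = "rows", digits = NA)
    }
    out
}

#' True clade of each fragment under a planting manifest
#'
#' Pure scaffolds inherit the scaffold clade; fragments of hybrid scaffolds
#' take the clade of the planted segment containing their midpoint
#' (Bacteria before the junction, Eukaryota after).
#'
#' @param manifest a planting manifest.
#' @param fragments fragment set from [fragmentAssembly()].
#' @return character vector of true clades, parallel to \code{fragments}.
#' @export
fragmentTruth <- function(manifest, fragments) {
    mc <- S4Vectors::mcols(fragments)
    i <- match(mc$scaffold_id, manifest$scaffold_id)
    if (anyNA(i))
        stop("fragment scaffold absent from the manifest")
    truth <- manifest$clade[i]
    hyb <- truth == "hybrid"
    mid <- (mc$start + mc$end + 1L) %/% 2L        # 1-based midpoint
    truth[hyb] <- ifelse(mid[hyb] <= manifest$junction[i[hyb]],
                         "Bacteria", "Eukaryota")
    truth
}

#' Generate a mock tabular hit file for planted fragments
#'
#' Each fragment emits, with probability \code{hitProb}, one intended
#' best-quality hit whose subject taxid is a leaf of the fragment's true
#' clade — flipped to the opposite clade with probability \code{noiseRate}
#' — plus 0-3 decoy hits that always trail the intended hit by at least 5
#' bitscore units, so best-hit selection recovers the intended hit by
#' construction.  Output is 13-column tabular BLAST (staxids in column 13),
#' deterministic under \code{seed}.
#'
#' @param manifest a planting manifest.
#' @param fragments fragment set from [fragmentAssembly()] over the matching
#'   assembly.
#' @param seed integer RNG seed.
#' @param path output path of the hit file.
#' @param hitProb probability a fragment has any hit (default 1).
#' @param noiseRate probability the intended hit points at the wrong clade
#'   (default 0).
#' @param leaves leaf-taxid list as returned by [makeTaxonomyFixture()].
#' @return \code{path}, invisibly, with the per-fragment truth table
#'   (fragment_id, true_clade, emitted_clade, has_hit) as
#'   \code{attr(, "truth")}.
#' @export
makeHitTable <- function(manifest, fragments, seed, path,
                         hitProb = 1, noiseRate = 0,
                         leaves = makeTaxonomyFixture()$leaves) {
    set.seed(as.integer(seed))
    truth <- fragmentTruth(manifest, fragments)
    n <- length(fragments)
    hasHit <- stats::runif(n) < hitProb
    flip <- stats::runif(n) < noiseRate
    emitted <- ifelse(flip, ifelse(truth == "Bacteria", "Eukaryota",
                                   "Bacteria"), truth)
    cladePool <- list(Bacteria = leaves$Bacteria,
                      Eukaryota = leaves$Phaeophyceae)
    allLeaves <- unlist(cladePool, use.names = FALSE)
    rows <- vector("list", n)
    for (i in which(hasHit)) {
        fid <- names(fragments)[i]
        w <- Biostrings::width(fragments)[i]
        pool <- cladePool[[emitted[i]]]
        taxid <- pool[sample.int(length(pool), 1L)]
        bestBit <- stats::runif(1L, 250, 500)
        alen <- sample(seq(100L, max(100L, w)), 1L)
        mkrow <- function(taxid, bit, ev) {
            sprintf("%s\tacc_%d_%d\t%.1f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%.3g\t%.1f\t%d",
                    fid, taxid, sample.int(1000L, 1L),
                    stats::runif(1L, 80, 100), alen,
                    sample.int(20L, 1L) - 1L, sample.int(3L, 1L) - 1L,
                    1L, alen, 1L, alen, ev, bit, taxid)
        }
        out <- mkrow(taxid, bestBit, 10^-stats::runif(1L, 20, 120))
        nDecoy <- sample.int(4L, 1L) - 1L
        for (k in seq_len(nDecoy)) {
            dtax <- allLeaves[sample.int(length(allLeaves), 1L)]
            dbit <- bestBit - 5 - stats::runif(1L, 0, 60)
            out <- c(out, mkrow(dtax, dbit, 10^-stats::runif(1L, 6, 15)))
        }
        rows[[i]] <- out
    }
    writeLines(as.character(unlist(rows)), path)
    tr <- data.frame(fragment_id = names(fragments), true_clade = truth,
                     emitted_clade = ifelse(hasHit, emitted, NA_character_),
                     has_hit = hasHit, stringsAsFactors = FALSE)
    out <- path
    attr(out, "truth") <- tr
    invisible(out)
}

#' Run the full pipeline on the demo study conditions
#'
#' Generates the miniature taxonomy, the default planted assembly
#' ([demoManifest()]) and its hit table, runs classification, segments the
#' ambiguous scaffolds and flags hybrids.  With \code{dir} set, all inputs
#' and both reports are written there.
#'
#' @param seed integer RNG seed driving every generator.
#' @param dir optional output directory.
#' @param hitProb,noiseRate hit-table emission parameters, see
#'   [makeHitTable()].
#' @param manifest planting manifest (default [demoManifest()]).
#' @return a list: \code{manifest}, \code{assembly}, \code{tree},
#'   \code{config}, \code{report}, \code{fragments}, \code{bestHits},
#'   \code{segmentations}, \code{hybrids}.
#' @export
runDemo <- function(seed = 42, dir = NULL, hitProb = 1, noiseRate = 0,
                    manifest = demoManifest()) {
    seed <- as.integer(seed)
    fixDir <- if (is.null(dir)) tempfile("taxfix") else file.path(dir, "taxdump")
    fix <- makeTaxonomyFixture(fixDir)
    tree <- loadTaxdump(fix$nodes, fix$merged)
    config <- cladeConfig(Eukaryota = 2759, Bacteria = 2)
    asm <- makeAssembly(manifest, seed = seed, dir = dir)
    fragments <- fragmentAssembly(asm$assembly, 500)
    hitsPath <- if (is.null(dir)) tempfile(fileext = ".tsv")
                else file.path(dir, "hits.tsv")
    makeHitTable(manifest, fragments, seed = seed + 1L, path = hitsPath,
                 hitProb = hitProb, noiseRate = noiseRate,
                 leaves = fix$leaves)
    hits <- readBlastTab(hitsPath)
    run <- screenAssembly(asm$assembly, hits, tree, config, fragLen = 500,
                          evalueCutoff = 0.01, threshold = 90)
    ambiguous <- classifiedIds(run$report, "ambiguous")
    segmentations <- lapply(ambiguous, function(id)
        segmentScaffold(asm$assembly[id]))
    names(segmentations) <- ambiguous
    hybrids <- flagHybrids(run$report, segmentations, run$fragments,
                           run$bestHits, tree, config)
    if (!is.null(dir)) {
        writeReport(run$report, file.path(dir, "report.tsv"))
        writeHybridReport(hybrids, file.path(dir, "hybrids.tsv"))
    }
    list(manifest = manifest, assembly = asm$assembly, tree = tree,
         config = config, report = run$report, fragments = run$fragments,
         bestHits = run$bestHits, segmentations = segmentations,
         hybrids = hybrids)
}
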