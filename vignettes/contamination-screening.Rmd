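---
title: "Screening assemblies for contaminant and hybrid scaffolds with taxoscreen"
author: "taxoscreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening assemblies for contaminant and hybrid scaffolds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxoscreen)
```

# The problem and the model

Assemblies of non-model organisms routinely retain foreign DNA: bacteria and
diatoms from biofilms in algal cultures are the canonical example. Two
failure modes make post-assembly screening hard. First, a similarity search
with a whole 500 kb scaffold is dominated by its most conserved stretches —
transposons, viral insertions, rRNA — which say little about the scaffold's
origin. Second, contaminant regions in eukaryote assemblies often lack
protein predictions entirely (PolyA-selected RNA-seq removes bacterial
transcripts from the evidence), so protein-based screens undercount them.

`taxoscreen` instead gives every stretch of sequence the same weight.  Each
scaffold is cut into consecutive windows of $L$ bp (default 500; the tail
remainder is kept as its own fragment, never discarded, because silently
dropping up to $L-1$ bp per scaffold would bias long-scaffold statistics).
Each fragment is searched independently against a reference database by an
*external* tool — the package reads standard 12/13-column tabular output and
never bundles a database — and contributes one vote: the taxon of its best
hit, defined as maximal bitscore after an e-value cutoff (bitscore, unlike
the e-value, is independent of database size; ties break by e-value, then
file order, so selection is deterministic).

Votes are resolved against an ordered set of user-chosen target clades
$(c_1, \ldots, c_k)$ — taxonomy subtrees such as Eukaryota (2759) vs
Bacteria (2), or diatoms (2836) vs brown algae (2870).  For scaffold $s$
with $n_s$ fragments whose best hit resolved in the taxonomy, the clade
percentages are $100\,n_{s,c}/n_s$ and the decision rule is

$$\text{class}(s) = \begin{cases} c & \text{if } 100\,n_{s,c}/n_s \ge T \\
\text{ambiguous} & \text{otherwise,} \end{cases} \qquad T = 90.$$

With disjoint clades and $T > 50$ at most one clade can qualify, so the
classification is unique; raising $T$ can only move scaffolds *into* the
ambiguous class, never out of it.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `fragLen` | 500 bp | fragment/window length; smaller gives finer spatial resolution but weaker hits |
| `minLength` | 2000 bp | scaffolds at or below this length are not screened (strictly greater-than filter); shorter scaffolds carry too few votes |
| `evalueCutoff` | 0.01 | inclusive e-value bound on hits; tightening to 1e-5 typically changes nothing because genuine cross-clade hits sit far below both |
| `threshold` | 90 % | inclusive classification threshold $T$ |
| `denominator` | "resolved" | percentage denominator: all fragments whose best hit resolved anywhere ("resolved"), or only those inside configured clades ("clades") |
| `minInformativeHits` | 1 | scaffolds with fewer denominator hits stay ambiguous; raise it to avoid classifying a 100 kb scaffold on one hit |

Design choices where the convention was genuinely open, and why:

* **Threshold comparison is inclusive** ($\ge 90$), and documented as such;
  the rule is usually quoted with both strict and inclusive wording.
* **Hits outside every configured clade** count as `"other"` and stay in
  the default denominator; hits whose taxid cannot be resolved are
  `"unresolved"` and leave the denominator but are always reported.  Both
  denominators are available because screens differ in whether viruses,
  archaea etc. should dilute the vote.
* **Overlapping clades are rejected** at validation (with an override):
  nested clades make percentages ambiguous.
* **Merged taxids** are redirected on lookup; deleted/unknown taxids become
  `"unresolved"`, never silently a clade.

# GC segmentation and hybrid scaffolds

Scaffolds that end up ambiguous are the interesting pool: they mix assembly
artifacts (chimeras) with genuine recent horizontal transfers.  Both leave a
compositional footprint when donor and host differ in GC content.
`segmentScaffold()` locates such shifts by recursive binary segmentation.
For a window with $n$ called bases, a split after position $p$ leaves
$n_L, n_R$ called bases with GC fractions $g_L, g_R$, and the divergence is

$$D(p) = \frac{n_L\, n_R}{n^2}\,(g_L - g_R)^2 .$$

The argmax over all admissible positions (both sides $\ge$ `minSegLen`,
default 10 kb) is computed exactly via prefix counts — $O(n)$ per level, no
sampling.  For the accept/reject decision the package uses the scale-free
score

$$S = \frac{n\,D(p)}{\bar p\,(1-\bar p)},$$

where $\bar p$ is the window GC: under a homogeneous window $S$ is
approximately the squared supremum of a standardized Brownian bridge over
the admissible range, so its null distribution is nearly independent of
window length and GC level, and one calibrated threshold can drive the
whole recursion.  A split is accepted when $S \ge$ `threshold`; recursion
continues on both sides and otherwise stops (`halt` records why:
`threshold`, `min-length`, or `max-depth`).

**Calibration.** The default threshold (18) is the 99.9th percentile of the
null maximum score, estimated by seeded simulation of homogeneous sequences
at GC 30–65 % and lengths 100 kb and 500 kb
(`scripts/calibrate-segmentation.R`).  The conservative quantile keeps the
realized false-split rate well below a 5 % budget at every segment length
the recursion can encounter, at no practical cost in power: a genuine
junction with a 5-point GC contrast and 20 kb sides already scores
$S \approx 160$, an order of magnitude above the threshold.  N and
ambiguity codes are excluded from all GC counts (numerator *and*
denominator), matching `gcContent()`.

`flagHybrids()` then re-votes fragments inside each segment (a fragment
belongs to the segment containing its midpoint — unambiguous for tiling
fragments) and applies the same $\ge T$ rule per segment.  A scaffold is
**hybrid** only when two segments classify to *different* clades; an
ambiguous scaffold with no breakpoint is reported `mixed-unsegmented`
(taxonomically mixed but compositionally uniform), and segments that are
individually ambiguous never flag.  Distinguishing chimera from horizontal
transfer needs evidence outside this package (read coverage across the
junction, PCR) and is deliberately out of scope.

# Per-class GC distributions

`classGCDistribution()` is the classic sanity check: the host genome should
show a narrow unimodal GC distribution while diverse contaminants show a
wide multimodal one.  Per-scaffold GC values are binned at 1 % (bins
centered on integer percents, so a composition peak at, say, 49 % falls
mid-bin rather than on a boundary), smoothed with a centered moving average
(window 3 bins), and modes are bin centers of strict local maxima; a
plateau of equal smoothed counts above both flanks counts as one mode at
its center.  The plateau rule matters: without it a peak straddling two
bins with exactly equal counts would report no mode at all.

# What the synthetic generator emulates — and what it does not

`demoManifest()`/`makeAssembly()`/`makeHitTable()` generate the study
conditions used throughout the tests: 50 host scaffolds (50 kb, 49 % GC),
40 bacterial contaminants (40 kb, cycling 30/38/53/64 % GC — diverse
phylogenetic origins), and 10 hybrids (40 kb bacterial + 40 kb host).
Scaffold lengths sit in the realistic 2 kb–500 kb range and are large
enough (80–100 fragments) that a 90 % vote is statistically meaningful
under 5 % per-fragment label noise.  Sequences are emitted i.i.d. per base
at the planted GC level; hit tables emit one intended best hit per fragment
(wrong-clade with probability `noiseRate`, absent with probability
`1 - hitProb`) plus 0–3 decoys that always trail by ≥ 5 bitscore units, so
best-hit selection is exercised but never decided by chance.  Everything is
byte-deterministic under a seed.

What this does **not** model: oligonucleotide structure (real genomes are
not i.i.d.), alignment-length/score correlations, database incompleteness
that varies by clade, repeat-induced cross-clade hits, and Ns at junctions.
Passing the planted-truth tests therefore shows the *pipeline logic* is
correct — votes, thresholds, segmentation, reporting — not that any
particular real assembly will separate as cleanly.

# Numerical and degenerate-input conventions

* Coordinates are 0-based half-open internally (fragment metadata),
  1-based inclusive in every human-facing report — the usual FASTA/BLAST
  reporting convention.
* Fragment ids are `"<scaffold_id>__<index>"`; scaffold ids containing
  `__` are rejected on input so the mapping stays invertible.
* `gcContent()` of a sequence with no called bases is `NA`, never 0; empty
  sequences are an error.
* Scaffolds shorter than `2 * minSegLen` yield a single-segment result, not
  an error; segment tie-breaks take the smallest split position.
* Integer-overflow traps in the divergence statistic are avoided by double
  arithmetic ($n_L n_R$ exceeds 32-bit range beyond ~46 kb windows).
* Report percentages are written with 2 decimals, "." decimal separator,
  LF endings, UTF-8; totals always equal the column sums of the rows
  (enforced by the class validity check).

# Problem sizes used in the shipped checks

The test-suite and acceptance script run the demo conditions above
(~4.9 Mb, ~9,800 fragments), one 504,453 bp two-part chimera
(79,743 bp at 40.7 % GC + 424,710 bp at 49.9 %), 200 homogeneous 100 kb
null replicates for the false-split rate, and 200 scaffolds for
GC-mode recovery — sizes chosen so a full run completes in minutes on one
core while every decision path of the pipeline is exercised.

# Known limitations

* Classification quality is bounded by the reference database: clades
  absent from it become `no_hits` or `other`, not their true origin.
* The GC segmentation only sees junctions with a composition contrast;
  a contaminant insertion at host-like GC is invisible to it (such
  scaffolds surface as `mixed-unsegmented`).
* No coverage-based evidence is used (no BAM input), and the package never
  edits the input FASTA — it emits classifications and keep-lists, leaving
  removal to the user's judgement.
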