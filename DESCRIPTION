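Package: taxoscreen
Title: Post-Assembly Detection of Contaminant and Hybrid Scaffolds
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Screens assembled genomes for foreign DNA after assembly.
    Scaffolds are split into short fixed-length fragments, each fragment is
    classified by the taxonomy of its best alignment hit (standard tabular
    BLAST input), and per-scaffold hit percentages against user-chosen target
    clades are summarized with an inclusive 90 percent decision rule.
    Scaffolds that cannot be attributed to a single clade are screened for
    within-scaffold GC-content segmentation points to flag hybrid (chimeric)
    scaffolds. Ships a seeded synthetic-assembly generator and a miniature
    NCBI-style taxonomy so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
biocViews: Sequencing, Classification, QualityControl, Assembly
Config/testthat/edition: 3
RoxygenNote: 7.3.3
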