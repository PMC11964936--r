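Package: parafates
Title: Paralogue Expression Fates and Dosage Constraint in Multi-Species Transcriptomes
Version: 0.1.0
Authors@R:
    person("pan-genome", "tools", email = "devnull@example.org", role = c("aut", "cre"))
Description: Tools for studying the expression evolution of retained gene
    duplicates across a clade from multi-tissue bulk RNA-seq. Builds
    per-species rank-standardized coexpression networks, classifies
    paralogue pairs into four expression-fate groups (dosage balanced,
    paralogue dominance, specialized, diverged), tests whether the summed
    expression dosage of two-copy orthogroups is conserved across species
    (Benjamini-Hochberg corrected cross-species z-tests on log dosage
    ratios), and annotates genes with expression breadth, tau tissue
    specificity, functional status and positional duplication type
    (tandem, proximal, dispersed). A synthetic multi-species expression
    simulator with planted ground truth makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    data.table,
    jsonlite,
    rtracklayer,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
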