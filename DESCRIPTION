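Package: treeharmony
Title: Phylogeny-Constrained Placement and Branch-Level Analysis of Somatic Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Places somatic single-nucleotide variants, structural variants and
    copy-number alterations from single-cell-derived tumor sublines onto the
    branches of a subline phylogeny, using clade-support thresholds derived
    from an assumed false-negative rate and loss-aware regenotyping of
    variants erased by deletions. Includes the supporting SNV filter cascade
    for building the tree-input genotype matrix, branch-level mutational
    signature timing and cumulative dN/dS, subclonal differential-methylation
    analysis with bipartition permutation tests and Mann-Kendall monotonic
    trajectory discovery, copy-number selection tests on oncogene and tumor
    suppressor labels, copy-neutral LOH timing, pseudobulk truth-set
    benchmarking, and a seeded synthetic-data generator so every stage runs
    without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    IRanges,
    GenomicRanges,
    S4Vectors,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
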