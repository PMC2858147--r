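Package: recombscan
Title: Recombination Detection, Genealogical Concordance Species
    Recognition and Border Scans for Multilocus Sequence Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting recombination in multilocus haploid
    sequence data and for delimiting phylogenetic species by genealogical
    concordance. Implements the pairwise homoplasy index (Phi) permutation
    test, the index of association on clone-corrected haplotypes, the
    partition-homogeneity (incongruence length difference) test with a
    built-in parsimony search, genealogical concordance phylogenetic
    species recognition over per-locus gene trees, an iterative Phi-based
    scan that locates the inner and outer borders of recombining
    populations, and population statistics (Hudson FST, Watterson theta,
    nucleotide diversity, Tajima's D, Hudson-Kaplan Rm). A Kingman
    coalescent simulator generates multilocus datasets with known clonal,
    panmictic, structured, intra-locus-recombining and border-scenario
    truth for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
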