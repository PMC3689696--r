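Package: ribohet
Title: Intragenomic Heterogeneity Analysis of rDNA Repeat Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of intragenomic sequence heterogeneity in cloned
    rDNA repeats (yeast 26S D1/D2 domains): variable-site and
    substitution-spectrum profiling of multiple alignments, detection of
    clustered variable regions, reconciliation of IUPAC-ambiguous database
    consensus sequences against clone pools, hairpin-aware classification
    of substitutions (G:U wobble-neutral, compensatory, disruptive) with a
    base-pair-maximization secondary-structure folder, distance-based
    phylogenetics (p, F84, K3ST distances; neighbor joining with bootstrap
    support), the pairwise homoplasy (Phi) recombination test with a
    permutation null, and a seeded simulator of rDNA repeat-array
    evolution (duplication, biased substitution, compensatory co-mutation,
    recombination, gene conversion, homogenization) that provides ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
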