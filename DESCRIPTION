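Package: msytree
Title: Haplotype Phylogenies and Haplogroup Assignment for the Male-Specific Y Chromosome
Version: 0.1.0
Authors@R:
    person("MSY", "Tools Contributors", email = "msytree@example.org", role = c("aut", "cre"))
Description: Tools for building haplotype phylogenies from polarized binary
    variants on the non-recombining, male-specific region of the Y chromosome
    (MSY). Implements perfect-phylogeny tree construction with per-branch
    diagnostic ("identifier") variants, a small-parsimony fallback for rare
    homoplasic characters, tree-guided imputation of missing genotypes,
    haplogroup assignment of modern samples from small diagnostic marker
    panels, placement of low-coverage ancient samples on a modern backbone by
    derived/ancestral identifier counting, group-wise diversity summaries
    (Watterson's theta, mean pairwise differences), molecular-clock node
    dating, and a coalescent/backbone simulator so every stage is testable
    against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    ape,
    jsonlite
Config/testthat/edition: 3
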