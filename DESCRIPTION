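Package: timpfam
Title: Gene-Family Phylogenetics and Abundance Analysis for TIMP Transcripts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for post-annotation analysis of tissue inhibitor of
    metalloproteinases (TIMP) gene families recovered from multi-specimen
    transcriptome assemblies. Provides divergence screening and duplicate
    removal, a deterministic progressive aligner, iterative overlap-based
    alignment culling over a grid of residue- and sequence-overlap
    thresholds, grid selection by taxon retention under a gap ceiling
    ('Boxer'), distance trees with bootstrap bipartition support, greedy
    rogue-terminal pruning by summed-support improvement, mean-path-length
    ultrametricization with lineages-through-time profiles and the
    Pybus-Harvey gamma statistic, threshold consensus and motif scanning,
    per-specimen abundance statistics, and a synthetic gene-family
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    Rcpp,
    jsonlite,
    phangorn,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
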