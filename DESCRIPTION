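Package: singletree
Title: Multi-Locus Phylogenies from Single-Copy Genes in Annotated Genomes
Version: 0.1.0
Authors@R:
    person("Singletree", "Developers", email = "singletree@example.org",
           role = c("aut", "cre"))
Description: Builds genome-scale, multi-locus phylogenetic trees directly from
    annotated GenBank flat files or per-genome protein FASTA files. Orthologues
    are identified de novo with a strict single-copy heuristic: genes that are
    singletons (no within-genome homologues) in a seed genome are screened
    across all genomes, and only loci that are single-copy everywhere are kept.
    Selected loci are aligned per locus, concatenated into a partitioned
    supermatrix, and a phylogeny is inferred with a built-in neighbour-joining
    backend or external maximum-likelihood tools (FastTree, IQ-TREE). Includes
    congruence and support metrics (parsimony-informative sites, branch-support
    summaries, Robinson-Foulds distances and a normalised-sum congruence
    statistic) and a synthetic-genome simulator with planted orthologue
    structure for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
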