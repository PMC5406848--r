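Package: coreflex
Title: Core and Flexible Genome Analysis for Experimental Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing molecular evolution in the laboratory with
    sequence diversity and divergence in nature. Partitions a bacterial genome
    collection into core (panorthologous) and flexible compartments by
    reciprocal-best-hit orthology, computes an amino-acid analogue of Nei's
    nucleotide diversity with an explicit indel convention, classifies and
    tallies synonymous and nonsynonymous mutations from evolution-experiment
    clone sequences, computes gene-level parallelism (G) scores, compartment
    enrichment odds ratios with exact binomial tests, count-based dN/dS with a
    configurable nonsynonymous-to-synonymous site ratio, and maps mutated
    residues onto protein structures using an 8 Angstrom interface-proximity
    criterion. Includes a fully seeded synthetic-data generator that emulates
    a pangenome, a mutation table, a gene-essentiality screen and toy
    multi-chain structures with known ground truth, so every stage of the
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    dplyr,
    igraph,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
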