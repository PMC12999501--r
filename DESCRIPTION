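Package: ddnetmap
Title: Delay-Discounting Gene Network Mapping by Propagation, Multiscale
    Communities, and Trait Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for mapping the biology around a set of
    trait-associated seed genes on a functional gene interaction network.
    Scores 27-item Monetary Choice Questionnaire responses into hyperbolic
    discounting rates k (and log10 k) with quality-control flags; propagates
    seed genes by random walk with restart and calibrates per-gene Network
    Proximity Scores (NPS) against degree-matched random seed ensembles;
    assembles a multiscale hierarchy of persistent communities linked by
    containment-index edges; and tests each community for trait gene-set
    over-representation with hypergeometric tests, odds ratios, and
    Benjamini-Hochberg FDR. Includes synthetic-data generators (planted
    partition networks, seed and trait gene-sets, simulated questionnaire
    responses) so the whole chain is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
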