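Package: tumorevol
Title: Population-Level Tumor Evolution Analysis from Expression, Copy Number
    and Mutation Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting the directionality of tumor evolution across
    pathological stages (normal, in situ, invasive, metastatic) from
    population-level molecular summaries. Implements multi-study differential
    expression meta-analysis with Fisher combination, classification of
    copy-number alteration frequency profiles into stage-transition prototypes,
    integration of gene-level alterations with prototype regions via per-megabase
    densities, matched-pair signed-rank tests for stage concordance and for
    forward and backward evolution models, signed-topology pathway perturbation
    analysis (net accumulation, bootstrap and over-representation p-values) with
    fine-tuning comparisons, protein-interaction hub homogeneity statistics,
    network-based driver-gene detection from mutation frequencies, binary-character
    maximum-parsimony phylogenies of stages, and iterative discriminative-feature
    selection with survival concordance analysis. A seeded synthetic-cohort
    generator with planted signals makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph,
    survival,
    ape,
    phangorn,
    GenomicRanges,
    IRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
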