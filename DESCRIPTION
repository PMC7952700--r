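Package: prynt
Title: Disease-Candidate Prioritization from Urinary Proteomics by
    Contextualized Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Prioritizes disease candidate proteins from a list of
    deregulated urinary proteins by mining a directed protein-protein
    interaction network. Builds contextualized variants of a STRING-style
    'protein.actions' network (seed injection and maximal-clique
    consolidation), scores every non-seed protein by a reciprocal
    shortest-path score and by random walk with restart, combines the two
    rankings by rank product, and evaluates rankings against reference
    disease-candidate lists with precision-at-k curves, trapezoidal AUC
    and cross/overall specificity. Includes a synthetic-study generator
    with planted cliques and planted candidate signal so the whole
    pipeline can be exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
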