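Package: kegg2net
Title: Gene Interaction Networks and Acyclic Graphs from KEGG Pathway Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts KGML pathway documents into directed gene-only
    interaction networks that preserve every direct and indirect gene-gene
    relation mediated by compounds, maps and other non-gene entries. Cyclic
    networks are converted to directed acyclic graphs by four alternative
    strategies: depth-first-search back-edge removal, the Eades-Lin-Smyth
    greedy minimum-feedback-arc-set heuristic, a PageRank-derived hierarchy,
    and an ensemble of TrueSkill and social-agony hierarchies. A seedable
    Hill-kinetics simulator generates steady-state expression data consistent
    with a network topology, and discrete multinomial BIC scoring compares
    each DAG against random DAGs with matched node and edge counts. Networks
    and DAGs read and write SIF and adjacency-matrix text formats; a
    synthetic-KGML fixture generator makes the whole pipeline testable
    without any KEGG download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xml2
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
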