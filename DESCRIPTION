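Package: bridgenet
Title: Candidate Gene Discovery by Bridging Disease Genes in
    Protein-Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds confidence-weighted protein-protein interaction (PPI)
    networks from scored edge tables (including the STRING protein-links
    dialect), classifies a disease gene list by network connectivity,
    selects one best intermediate ("bridge") gene for each disconnected
    gene as a novel-gene candidate, propagates cellular-localization group
    labels by iterated PPI-count majority from a seed assignment, and
    summarises inter- and intragroup connectivity. Ships a planted-partition
    synthetic network generator with planted bridges so the whole protocol
    is testable offline, plus annotated GraphML/DOT/TSV export and a small
    command-line front end.
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
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
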