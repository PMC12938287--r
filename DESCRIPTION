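Package: inflammate
Title: Agent-Based Inflammation Simulation and Transfer-Entropy Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates acute inflammation and inflammaging on a 2D lattice
    with macrophage and fibroblast agents, diffusing TNF and TGF cytokine
    fields and an epithelial tissue layer, then quantifies cell-cell
    information exchange from migration turning angles. Provides histogram
    plug-in estimators of Shannon entropy, mutual information, conditional
    mutual information and transfer entropy; builds bipartite
    macrophage-fibroblast transfer-entropy networks with a quartile edge
    criterion; and summarises inflammation course and network topology
    (betweenness-centrality balance) across stimulus levels and aging
    presets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
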