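Package: bosnet
Title: Asymmetric Coordination Games on Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of iterated asymmetric ("Battle of the
    Sexes") coordination games played on networks. Generates connected
    Erdos-Renyi, Watts-Strogatz small-world and Barabasi-Albert
    preferential-attachment graphs with balanced preference assignments, runs
    probabilistic (and deterministic) myopic best-response dynamics on a
    discrete probability grid, and measures the resulting global behaviour
    (proportion of nodes on each convention, behavioural heterogeneity,
    Walktrap modularity) and local positional advantage (per-node Power,
    centralities, even-degree effects). Includes the full experiment
    orchestration, descriptive and kernel-regression summaries, and
    cross-validated backward-selected OLS models of node Power with
    intraclass correlation diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
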