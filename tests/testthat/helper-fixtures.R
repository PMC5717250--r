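# Small graph fixtures built in code.

# Two k-cliques joined by a single bridge edge (nodes 1..k and k+1..2k).
two_cliques <- function(k) {
  clique <- t(utils::combn(k, 2))
  edges <- rbind(clique, clique + k, c(k, k + 1))
  igraph::graph_from_edgelist(edges, directed = FALSE)
}

# Minimal bos_design-shaped object for analysis-layer tests that do not need
# a simulation: caller supplies the tables it uses.
fake_design <- function(games = NULL, networks = NULL, nodes = NULL,
                        power = NULL, community_outcomes = NULL) {
  structure(list(config = design_config(scale = 0.001),
                 games = games, networks = networks, nodes = nodes,
                 node_structure = NULL, power = power,
                 community_outcomes = community_outcomes, graphs = NULL),
            class = "bos_design")
}
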