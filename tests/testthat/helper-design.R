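# Shared simulation runs for the acceptance checks, built once per test run.
#
# Problem sizes: a 1/10-scale replication of the full design (100 ER, 20 WS
# per rewiring level, 100 PA networks; 30 preference configurations each;
# S = 0.9) for the global statistics, and single-family runs at the study's
# 100 configurations per network for the Power-based statistics, whose
# estimator granularity (1/configs) the regression fits are sensitive to.

.acceptance_cache <- new.env(parent = emptyenv())

acceptance_design <- function() {
  if (is.null(.acceptance_cache$mix)) {
    .acceptance_cache$mix <- run_design(design_config(
      n_er = 100, n_sw = 100, n_pa = 100, configs_per_network = 30,
      S_values = 0.9, seed = 1001L))
  }
  .acceptance_cache$mix
}

# Mean Walktrap modularity is a purely structural statistic (no games are
# involved), so it is estimated at the study's full network count
# (1000 per family) where its Monte-Carlo error is ~0.0015.
acceptance_modularity <- function() {
  if (is.null(.acceptance_cache$modularity)) {
    set.seed(4004L)
    q <- c(
      replicate(1000, {
        g <- generate_er(20, 0.2)
        graph_modularity(g, walktrap_communities(g))
      }),
      vapply(rep(c(0.05, 0.1, 0.15, 0.2, 0.25), each = 200), function(p) {
        g <- generate_ws(20, 4, p)
        graph_modularity(g, walktrap_communities(g))
      }, numeric(1)),
      replicate(1000, {
        g <- generate_pa(20, 2)
        graph_modularity(g, walktrap_communities(g))
      }))
    .acceptance_cache$modularity <- mean(q)
  }
  .acceptance_cache$modularity
}

acceptance_family <- function(family) {
  key <- paste0("fam_", family)
  if (is.null(.acceptance_cache[[key]])) {
    .acceptance_cache[[key]] <- run_design(design_config(
      n_er = if (family == "ER") 100 else 0,
      n_sw = 0,
      n_pa = if (family == "PA") 100 else 0,
      configs_per_network = 100, S_values = 0.9,
      seed = if (family == "ER") 2002L else 3003L))
  }
  .acceptance_cache[[key]]
}
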