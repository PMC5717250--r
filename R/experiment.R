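#' Configuration of a full simulation design
#'
#' The default design mirrors the full study: 1000 Erdos-Renyi networks
#' (\eqn{G(20, 0.2)}), 1000 Watts-Strogatz small-world networks split equally
#' over the rewiring probabilities `p_sm_values`, and 1000 preferential
#' attachment networks (`m_pa = 2`), each connected, each with 100 balanced
#' random preference configurations, each configuration played once per value
#' of `S`. `scale` rescales the network counts and configurations per network
#' proportionally for desk-scale runs without touching any estimator
#' definition; per-network and per-game child seeds are drawn deterministically
#' from `seed`, and the same game seed is reused across `S` values so
#' comparisons in `S` are paired.
#'
#' @param n_er,n_sw,n_pa Networks per family (`n_sw` is split equally over
#'   `p_sm_values`).
#' @param p_sm_values Rewiring probabilities for the WS family.
#' @param configs_per_network Balanced preference configurations per network.
#' @param S_values Off-preference payoffs to cross with every game.
#' @param n,n_alpha Nodes per network and alpha-types per configuration.
#' @param p_er,k_ws,m_pa Family parameters (see [network_spec()]).
#' @param step,t_min,t_max,rule Game parameters (see [game_params()]).
#' @param seed Root seed for the whole design.
#' @param scale Proportional rescaling factor for counts (e.g. 0.1).
#' @return An object of class `design_config`.
#' @examples
#' design_config(scale = 0.01, S_values = 0.9)
#' @export
design_config <- function(n_er = 1000L, n_sw = 1000L, n_pa = 1000L,
                          p_sm_values = c(0.05, 0.1, 0.15, 0.2, 0.25),
                          configs_per_network = 100L,
                          S_values = c(0.9, 0.7, 0.5),
                          n = 20L, n_alpha = n %/% 2L,
                          p_er = 0.2, k_ws = 4L, m_pa = 2L,
                          step = 0.1, t_min = 10L, t_max = 100L,
                          rule = "probabilistic",
                          seed = 1L, scale = 1) {
  stopifnot(scale > 0, length(p_sm_values) >= 1, length(S_values) >= 1)
  # zero disables a family; any positive count survives rescaling
  rescale <- function(x)
    if (x == 0) 0L else max(1L, as.integer(round(x * scale)))
  n_sw_per_p <- rescale(n_sw / length(p_sm_values))
  cfg <- list(
    n_er = rescale(n_er),
    n_sw_per_p = n_sw_per_p,
    n_pa = rescale(n_pa),
    p_sm_values = p_sm_values,
    configs_per_network = rescale(configs_per_network),
    S_values = S_values,
    n = as.integer(n), n_alpha = as.integer(n_alpha),
    p_er = p_er, k_ws = as.integer(k_ws), m_pa = as.integer(m_pa),
    step = step, t_min = as.integer(t_min), t_max = as.integer(t_max),
    rule = rule,
    seed = as.integer(seed), scale = scale)
  class(cfg) <- "design_config"
  cfg
}

#' @export
print.design_config <- function(x, ...) {
  cat(sprintf(
    paste0("<design_config> %d ER + %d x %d WS + %d PA networks, ",
           "%d configs each, S in {%s}, n = %d, seed = %d\n"),
    x$n_er, length(x$p_sm_values), x$n_sw_per_p, x$n_pa,
    x$configs_per_network, paste(x$S_values, collapse = ", "),
    x$n, x$seed))
  invisible(x)
}

## Expand a design_config into one row per network with its family parameters.
design_network_plan <- function(cfg) {
  fam <- c(rep("ER", cfg$n_er),
           rep("WS", cfg$n_sw_per_p * length(cfg$p_sm_values)),
           rep("PA", cfg$n_pa))
  p_sm <- c(rep(NA_real_, cfg$n_er),
            rep(cfg$p_sm_values, each = cfg$n_sw_per_p),
            rep(NA_real_, cfg$n_pa))
  data.frame(network_id = seq_along(fam), family = fam, p_sm = p_sm)
}

#' Run the full simulation design
#'
#' For every planned network: generate the graph, compute its structural
#' metrics once (centralities, Walktrap communities, modularity); then for
#' each preference configuration and each `S`, run one iterated game and
#' record the global outcome, the per-node records and the per-community
#' outcome proportions. Per-node Power is aggregated per network and `S`
#' over the configurations. Deterministic given the root seed.
#'
#' @param cfg A [design_config()].
#' @param keep_graphs If `TRUE`, retain the generated igraph objects in the
#'   result (needed for [write_design()]'s GraphML dump).
#' @param progress Print a progress line every `progress` networks (0 = quiet).
#' @return An object of class `bos_design`: a list of data.frames `networks`
#'   (one row per network: family, p_sm, seed, modularity, community count),
#'   `games` (one row per network x configuration x S), `nodes` (one row per
#'   game x node), `node_structure` (one row per network x node), `power`
#'   (one row per network x S x node, structural variables joined on), and
#'   `community_outcomes` (one row per game x community), plus the `config`.
#' @examples
#' d <- run_design(design_config(scale = 0.005, S_values = 0.9, seed = 42))
#' d
#' @export
run_design <- function(cfg, keep_graphs = FALSE, progress = 0L) {
  stopifnot(inherits(cfg, "design_config"))
  plan <- design_network_plan(cfg)
  n_net <- nrow(plan)
  n_cfg <- cfg$configs_per_network
  set.seed(cfg$seed)
  seed_max <- .Machine$integer.max - 1L
  net_seeds <- sample.int(seed_max, n_net)
  pref_seeds <- matrix(sample.int(seed_max, n_net * n_cfg), n_net, n_cfg)
  game_seeds <- matrix(sample.int(seed_max, n_net * n_cfg), n_net, n_cfg)

  params_by_S <- lapply(cfg$S_values, function(S)
    game_params(S = S, step = cfg$step, t_min = cfg$t_min,
                t_max = cfg$t_max, rule = cfg$rule))

  net_rows <- vector("list", n_net)
  game_rows <- vector("list", n_net)
  node_rows <- vector("list", n_net)
  struct_rows <- vector("list", n_net)
  power_rows <- vector("list", n_net)
  comm_rows <- vector("list", n_net)
  graphs <- if (keep_graphs) vector("list", n_net) else NULL

  for (i in seq_len(n_net)) {
    fam <- plan$family[i]
    set.seed(net_seeds[i])
    g <- switch(fam,
      ER = generate_er(cfg$n, cfg$p_er),
      WS = generate_ws(cfg$n, cfg$k_ws, plan$p_sm[i]),
      PA = generate_pa(cfg$n, cfg$m_pa))
    if (keep_graphs) graphs[[i]] <- g
    cent <- node_centralities(g)
    memb <- walktrap_communities(g)
    Q <- graph_modularity(g, memb)
    net_rows[[i]] <- data.frame(
      network_id = i, family = fam, p_sm = plan$p_sm[i],
      seed = net_seeds[i], n_nodes = cfg$n, n_edges = igraph::ecount(g),
      modularity = Q, n_communities = length(unique(memb)))
    struct_rows[[i]] <- cbind(network_id = i, cent, community = memb)

    n_S <- length(cfg$S_values)
    prop_a <- het <- conv <- rounds <- numeric(n_cfg * n_S)
    S_col <- cfg_col <- seed_col <- numeric(n_cfg * n_S)
    pref_list <- vector("list", n_cfg)
    Ln_list <- vector("list", n_cfg)
    Lc_list <- vector("list", n_cfg)
    preferred <- array(NA, dim = c(n_cfg, cfg$n, n_S))
    comm_local <- vector("list", n_cfg * n_S)
    row <- 0L
    for (cidx in seq_len(n_cfg)) {
      set.seed(pref_seeds[i, cidx])
      prefs <- assign_preferences(cfg$n, cfg$n_alpha)
      pref_list[[cidx]] <- prefs
      Ln_list[[cidx]] <- local_pref_neighbors(g, prefs)
      Lc_list[[cidx]] <- local_pref_community(memb, prefs)
      for (sidx in seq_len(n_S)) {
        row <- row + 1L
        set.seed(game_seeds[i, cidx])  # same seed across S: paired draws
        res <- run_game(g, prefs, params_by_S[[sidx]])
        out <- outcome_measures(res, prefs, memb)
        prop_a[row] <- out$proportion_alpha
        het[row] <- out$heterogeneity
        conv[row] <- res$converged
        rounds[row] <- res$rounds
        S_col[row] <- cfg$S_values[sidx]
        cfg_col[row] <- cidx
        seed_col[row] <- game_seeds[i, cidx]
        preferred[cidx, , sidx] <- out$preferred
        comm_local[[row]] <- data.frame(
          network_id = i, config = cidx, S = cfg$S_values[sidx],
          community = sort(unique(memb)),
          size = as.integer(table(memb)),
          prop_alpha = out$community_prop_alpha)
      }
    }
    game_rows[[i]] <- data.frame(
      network_id = i, family = fam, p_sm = plan$p_sm[i],
      config = cfg_col, S = S_col, seed = seed_col,
      proportion_alpha = prop_a, heterogeneity = het,
      converged = as.logical(conv), rounds = as.integer(rounds))
    node_rows[[i]] <- data.frame(
      network_id = i,
      config = rep(rep(seq_len(n_cfg), each = cfg$n), n_S),
      S = rep(cfg$S_values, each = n_cfg * cfg$n),
      node = rep(seq_len(cfg$n), n_cfg * n_S),
      preference = rep(unlist(pref_list), n_S),
      preferred = as.vector(vapply(seq_len(n_S), function(s)
        as.vector(t(preferred[, , s])), numeric(n_cfg * cfg$n))) == 1,
      L_n = rep(unlist(Ln_list), n_S),
      L_c = rep(unlist(Lc_list), n_S))
    power_rows[[i]] <- do.call(rbind, lapply(seq_len(n_S), function(s)
      data.frame(network_id = i, family = fam, p_sm = plan$p_sm[i],
                 S = cfg$S_values[s], node = seq_len(cfg$n),
                 power = colMeans(matrix(preferred[, , s], nrow = n_cfg)))))
    comm_rows[[i]] <- do.call(rbind, comm_local)
    if (progress > 0L && i %% progress == 0L)
      message(sprintf("network %d/%d (%s)", i, n_net, fam))
  }

  node_structure <- do.call(rbind, struct_rows)
  power <- do.call(rbind, power_rows)
  power <- merge(power, node_structure, by = c("network_id", "node"),
                 sort = FALSE)
  power <- power[order(power$S, power$network_id, power$node), ]
  rownames(power) <- NULL
  out <- list(config = cfg,
              networks = do.call(rbind, net_rows),
              games = do.call(rbind, game_rows),
              nodes = do.call(rbind, node_rows),
              node_structure = node_structure,
              power = power,
              community_outcomes = do.call(rbind, comm_rows),
              graphs = graphs)
  class(out) <- "bos_design"
  out
}

#' @export
print.bos_design <- function(x, ...) {
  cat(sprintf(
    "<bos_design> %d networks, %d games (%d nodes each), S in {%s}\n",
    nrow(x$networks), nrow(x$games), x$config$n,
    paste(x$config$S_values, collapse = ", ")))
  cat(sprintf("  families: %s\n",
              paste(sprintf("%s=%d", names(table(x$networks$family)),
                            table(x$networks$family)), collapse = ", ")))
  invisible(x)
}

#' @export
summary.bos_design <- function(object, ...) {
  descriptives(object)
}

#' Write the result tables of a design run
#'
#' One CSV per table (`networks`, `games`, `nodes`, `power`,
#' `community_outcomes`) plus a `manifest.json` holding the configuration and
#' root seed. With `graphml = TRUE` (requires `run_design(keep_graphs =
#' TRUE)`) each generated network is also dumped as GraphML.
#'
#' @param design A `bos_design`.
#' @param dir Output directory (created if missing).
#' @param graphml Also dump each network as GraphML.
#' @return `dir`, invisibly.
#' @export
write_design <- function(design, dir, graphml = FALSE) {
  stopifnot(inherits(design, "bos_design"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (tab in c("networks", "games", "nodes", "power", "community_outcomes"))
    utils::write.csv(design[[tab]], file.path(dir, paste0(tab, ".csv")),
                     row.names = FALSE)
  manifest <- design$config
  class(manifest) <- NULL
  manifest$package_version <- as.character(utils::packageVersion("bosnet"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (graphml) {
    if (is.null(design$graphs))
      stop("re-run run_design() with keep_graphs = TRUE for a GraphML dump")
    gdir <- file.path(dir, "graphs")
    if (!dir.exists(gdir)) dir.create(gdir)
    for (i in seq_along(design$graphs))
      write_network(design$graphs[[i]],
                    file.path(gdir, sprintf("network_%04d.graphml", i)))
  }
  invisible(dir)
}
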