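#' Node centralities and the even-degree indicator
#'
#' Computes, for every node of a connected graph: normalized degree
#' centrality \eqn{k_i/(n-1)}; eigenvector centrality scaled so the maximum
#' entry is 1; shortest-path betweenness normalized by \eqn{(n-1)(n-2)/2}
#' (endpoints excluded); closeness as \eqn{(n-1)/\sum_j d(i,j)}; and `even`,
#' the indicator that the raw degree \eqn{k_i} is even. Even-degree nodes
#' need only half of their neighbourhood to coordinate for their preferred
#' convention to be a best reply, so `even` enters the Power regressions as
#' a predictor in its own right.
#'
#' @param g A connected igraph graph.
#' @return A data.frame with columns `node`, `degree_raw`, `degree`,
#'   `eigenvector`, `betweenness`, `closeness`, `even` (0/1).
#' @examples
#' head(node_centralities(generate_pa(20, 2)))
#' @export
node_centralities <- function(g) {
  if (!igraph::is_connected(g)) stop("centralities require a connected graph")
  n <- igraph::vcount(g)
  k <- igraph::degree(g)
  ev <- igraph::eigen_centrality(g)$vector
  ev <- ev / max(ev)  # convention: maximum entry 1
  btw <- igraph::betweenness(g, normalized = TRUE)
  cls <- igraph::closeness(g, normalized = TRUE)
  data.frame(node = seq_len(n),
             degree_raw = as.integer(k),
             degree = k / (n - 1),
             eigenvector = ev,
             betweenness = btw,
             closeness = cls,
             even = as.integer(k %% 2 == 0))
}

#' Walktrap community detection
#'
#' Pons-Latapy random-walk communities: `walk_length`-step random-walk
#' probability profiles define pairwise node distances that are merged
#' agglomeratively; the merge tree is cut at the partition of maximal
#' modularity.
#'
#' @param g A connected igraph graph.
#' @param walk_length Random-walk length (default 4, the Pons-Latapy
#'   default).
#' @return An integer membership vector (community ids starting at 1).
#' @examples
#' g <- generate_ws(20, 4, 0.05)
#' table(walktrap_communities(g))
#' @export
walktrap_communities <- function(g, walk_length = 4L) {
  if (!igraph::is_connected(g)) stop("g must be connected")
  wt <- igraph::cluster_walktrap(g, steps = walk_length)
  as.integer(igraph::membership(wt))
}

#' Newman modularity of a partition
#'
#' \deqn{Q = \frac{1}{2m} \sum_{ij} \left[A_{ij} - \frac{k_i k_j}{2m}\right]
#'   \delta(c_i, c_j),}
#' the fraction of within-community edges minus its expectation under a
#' degree-preserving random rewiring, with \eqn{2m} the total degree.
#'
#' @param g An igraph graph.
#' @param membership Integer community membership vector covering every node.
#' @return The modularity score (always `< 1`; can be negative).
#' @examples
#' g <- generate_ws(20, 4, 0.05)
#' graph_modularity(g, walktrap_communities(g))
#' @export
graph_modularity <- function(g, membership) {
  stopifnot(length(membership) == igraph::vcount(g))
  igraph::modularity(g, membership)
}

#' Fraction of same-preference neighbours
#'
#' For each node, the fraction of its neighbours sharing its preference:
#' \eqn{L^n_i = \sum_j A_{ij}\,\delta(pr_i, pr_j) / \sum_j A_{ij}}.
#'
#' @param g A connected igraph graph (so every degree is at least 1).
#' @param prefs Character preference vector.
#' @return Numeric vector in \eqn{[0,1]}, one entry per node.
#' @export
local_pref_neighbors <- function(g, prefs) {
  stopifnot(length(prefs) == igraph::vcount(g))
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  same <- outer(prefs, prefs, "==")
  rowSums(A * same) / rowSums(A)
}

#' Fraction of same-preference nodes in a node's community
#'
#' \eqn{L^c_i = \sum_{j \ne i} \delta(c_i, c_j)\,\delta(pr_i, pr_j) /
#' \sum_{j \ne i} \delta(c_i, c_j)}: the fraction of the *other* members of
#' `i`'s community sharing `i`'s preference. A node in a singleton community
#' scores 1 by convention (it trivially agrees with its whole community).
#'
#' @param membership Integer community membership vector.
#' @param prefs Character preference vector of the same length.
#' @return Numeric vector in \eqn{[0,1]}, one entry per node.
#' @export
local_pref_community <- function(membership, prefs) {
  stopifnot(length(membership) == length(prefs))
  vapply(seq_along(membership), function(i) {
    others <- which(membership == membership[i])
    others <- others[others != i]
    if (length(others) == 0L) return(1)
    mean(prefs[others] == prefs[i])
  }, numeric(1))
}

#' Behavioural heterogeneity index
#'
#' \eqn{h(p_\alpha) = p_\alpha (1 - p_\alpha)}: the variance of the Bernoulli
#' indicator "node plays alpha" across the network. 0 at homogeneous
#' outcomes, maximal (0.25) at an even split; symmetric under relabelling
#' the conventions.
#'
#' @param p_alpha Proportion(s) of nodes playing alpha.
#' @return Heterogeneity value(s) in \eqn{[0, 0.25]}.
#' @export
heterogeneity <- function(p_alpha) {
  stopifnot(all(p_alpha >= 0 & p_alpha <= 1))
  p_alpha * (1 - p_alpha)
}

#' Outcome measures of a converged game
#'
#' Global proportion of nodes playing alpha, its heterogeneity, the per-node
#' `Preferred` flag (final action equals own preference), and the
#' per-community proportions of alpha play (communities detected once per
#' graph, used for the within-community outcome histogram).
#'
#' @param result A `bos_game` from [run_game()].
#' @param prefs Character preference vector used in the game.
#' @param membership Integer community membership vector.
#' @return A list with `proportion_alpha`, `heterogeneity`, `preferred`
#'   (logical vector), `community_prop_alpha` (one entry per community).
#' @export
outcome_measures <- function(result, prefs, membership) {
  stopifnot(inherits(result, "bos_game"))
  p_alpha <- result$proportion_alpha
  comm <- tapply(result$final_action == "alpha", membership, mean)
  list(proportion_alpha = p_alpha,
       heterogeneity = heterogeneity(p_alpha),
       preferred = result$final_action == prefs,
       community_prop_alpha = as.numeric(comm))
}

#' Node Power: preferred-equilibrium rate over preference configurations
#'
#' Power aggregates `Preferred` over the preference configurations played on
#' one network: per node, the fraction of configurations in which the node's
#' converged action was its own preferred convention. 0.5 means position is
#' uninformative; 1 means the node always gets its way.
#'
#' @param preferred_flags A configurations x nodes logical (or 0/1) matrix of
#'   `Preferred` flags.
#' @return Numeric vector of per-node Power values in \eqn{[0,1]}.
#' @examples
#' node_power(rbind(c(TRUE, FALSE), c(TRUE, TRUE)))  # 1.0 0.5
#' @export
node_power <- function(preferred_flags) {
  m <- as.matrix(preferred_flags)
  if (nrow(m) < 1) stop("at least one configuration is required")
  colMeans(m)
}
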