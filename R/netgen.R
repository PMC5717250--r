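#' Network specification
#'
#' Bundles the parameters of one of the three supported random-graph families
#' into a validated object that [generate_network()] can consume and that can
#' be round-tripped through a JSON/YAML experiment configuration.
#'
#' @param family One of `"ER"` (Erdos-Renyi \eqn{G(n, p)}), `"WS"`
#'   (Watts-Strogatz small world) or `"PA"` (Barabasi-Albert preferential
#'   attachment).
#' @param n Number of nodes (default 20).
#' @param p_er Edge probability for the ER family (default 0.2).
#' @param k_ws Ring-lattice degree for the WS family; must be even and at
#'   least 2 (default 4, i.e. two neighbours on each side).
#' @param p_sm Rewiring probability for the WS family.
#' @param m_pa Edges added per new node for the PA family (default 2).
#' @param seed Optional integer seed stored alongside the parameters.
#' @return An object of class `network_spec`.
#' @examples
#' network_spec("WS", p_sm = 0.1)
#' @export
network_spec <- function(family = c("ER", "WS", "PA"), n = 20L,
                         p_er = 0.2, k_ws = 4L, p_sm = 0.1, m_pa = 2L,
                         seed = NULL) {
  family <- match.arg(family)
  n <- as.integer(n)
  stopifnot(n >= 2L)
  if (family == "ER" && (p_er <= 0 || p_er >= 1))
    stop("p_er must lie strictly between 0 and 1")
  if (family == "WS") {
    k_ws <- as.integer(k_ws)
    if (k_ws < 2L || k_ws %% 2L != 0L) stop("k_ws must be even and >= 2")
    if (n <= k_ws) stop("n must exceed k_ws")
    if (p_sm < 0 || p_sm > 1) stop("p_sm must lie in [0, 1]")
  }
  if (family == "PA") {
    m_pa <- as.integer(m_pa)
    if (m_pa < 1L || m_pa >= n) stop("m_pa must satisfy 1 <= m_pa < n")
  }
  structure(list(family = family, n = n, p_er = p_er, k_ws = k_ws,
                 p_sm = p_sm, m_pa = m_pa, seed = seed),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  par_str <- switch(x$family,
    ER = sprintf("p_er = %g", x$p_er),
    WS = sprintf("k_ws = %d, p_sm = %g", x$k_ws, x$p_sm),
    PA = sprintf("m_pa = %d", x$m_pa))
  cat(sprintf("<network_spec> %s, n = %d, %s\n", x$family, x$n, par_str))
  invisible(x)
}

#' Generate a network from a specification
#'
#' Dispatches to [generate_er()], [generate_ws()] or [generate_pa()]. If the
#' spec carries a seed, the R random stream is seeded first so regeneration is
#' bit-identical.
#'
#' @param spec A [network_spec()].
#' @param max_tries Rejection budget for the connectivity constraint.
#' @return A connected, simple, undirected [igraph::igraph] graph with graph
#'   attributes `family` and the generating parameters.
#' @export
generate_network <- function(spec, max_tries = 10000L) {
  stopifnot(inherits(spec, "network_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  g <- switch(spec$family,
    ER = generate_er(spec$n, spec$p_er, max_tries = max_tries),
    WS = generate_ws(spec$n, spec$k_ws, spec$p_sm, max_tries = max_tries),
    PA = generate_pa(spec$n, spec$m_pa))
  g
}

## Build an igraph graph from a 2-column edge matrix and stamp attributes.
as_bos_graph <- function(el, n, family, ...) {
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  igraph::graph_attr(g, "family") <- family
  extra <- list(...)
  for (nm in names(extra)) igraph::graph_attr(g, nm) <- extra[[nm]]
  g
}

#' Connected Erdos-Renyi graph
#'
#' Draws each of the \eqn{n(n-1)/2} unordered node pairs independently with
#' probability `p_er` and rejects draws that are not connected, resampling
#' until a connected graph appears (disconnected graphs never enter the
#' study).
#'
#' @param n Number of nodes.
#' @param p_er Edge probability, strictly between 0 and 1.
#' @param max_tries Rejection budget; exceeded budgets signal parameters for
#'   which connectivity is vanishingly rare.
#' @return A connected simple undirected igraph graph.
#' @examples
#' g <- generate_er(20, 0.2)
#' igraph::is_connected(g)
#' @export
generate_er <- function(n, p_er, max_tries = 10000L) {
  n <- as.integer(n)
  stopifnot(n >= 2L)
  if (p_er <= 0 || p_er >= 1) stop("p_er must lie strictly between 0 and 1")
  pairs <- which(upper.tri(matrix(0L, n, n)), arr.ind = TRUE)
  for (i in seq_len(max_tries)) {
    keep <- stats::runif(nrow(pairs)) < p_er
    g <- as_bos_graph(pairs[keep, , drop = FALSE], n, "ER", p_er = p_er)
    if (igraph::is_connected(g)) return(g)
  }
  stop(sprintf(
    "no connected G(%d, %g) draw within %d attempts", n, p_er, max_tries))
}

#' Connected Watts-Strogatz small-world graph
#'
#' Starts from a ring lattice in which every node is linked to its `k_ws`
#' nearest ring neighbours (`k_ws/2` on each side) and rewires each lattice
#' edge independently with probability `p_sm`: the far endpoint is redirected
#' to a uniformly chosen node, avoiding self-loops and duplicate edges.
#' Disconnected outcomes are rejected and redrawn. Lower `p_sm` preserves the
#' lattice's clustering and community structure; at `p_sm = 1` the graph
#' resembles an Erdos-Renyi draw of equal density in its clustering.
#'
#' @param n Number of nodes.
#' @param k_ws Even lattice degree, `n > k_ws`.
#' @param p_sm Rewiring probability in \eqn{[0, 1]}.
#' @param max_tries Rejection budget for connectivity.
#' @return A connected simple undirected igraph graph.
#' @examples
#' g <- generate_ws(20, 4, 0.05)
#' table(igraph::degree(generate_ws(20, 4, 0)))  # pure lattice: all degree 4
#' @export
generate_ws <- function(n, k_ws, p_sm, max_tries = 10000L) {
  n <- as.integer(n); k_ws <- as.integer(k_ws)
  if (k_ws < 2L || k_ws %% 2L != 0L) stop("k_ws must be even and >= 2")
  if (n <= k_ws) stop("n must exceed k_ws")
  if (p_sm < 0 || p_sm > 1) stop("p_sm must lie in [0, 1]")
  half <- k_ws %/% 2L
  # lattice edges as (i, i + d mod n), d = 1..half; i is kept, the far
  # endpoint is the rewiring candidate
  from <- rep(seq_len(n), half)
  to0 <- as.integer((from - 1L + rep(seq_len(half), each = n)) %% n + 1L)
  for (try in seq_len(max_tries)) {
    adj <- matrix(FALSE, n, n)
    adj[cbind(from, to0)] <- TRUE
    adj[cbind(to0, from)] <- TRUE
    to <- to0
    rewire <- stats::runif(length(from)) < p_sm
    for (e in which(rewire)) {
      i <- from[e]
      candidates <- which(!adj[i, ] & seq_len(n) != i)
      if (length(candidates) == 0L) next  # node saturated; keep the edge
      j <- candidates[sample.int(length(candidates), 1L)]
      adj[i, to[e]] <- adj[to[e], i] <- FALSE
      adj[i, j] <- adj[j, i] <- TRUE
      to[e] <- j
    }
    g <- as_bos_graph(cbind(from, to), n, "WS", k_ws = k_ws, p_sm = p_sm)
    if (igraph::is_connected(g)) return(g)
  }
  stop(sprintf(
    "no connected WS(%d, %d, %g) draw within %d attempts",
    n, k_ws, p_sm, max_tries))
}

#' Barabasi-Albert preferential-attachment graph
#'
#' Growth with degree-proportional attachment: the seed graph is
#' \eqn{m_0 = m_{pa}} nodes (for the default `m_pa = 2`, two nodes joined by
#' an edge); each arriving node attaches `m_pa` distinct edges to existing
#' nodes sampled with probability proportional to their current degree, until
#' `n` nodes exist. The result is connected by construction.
#'
#' @param n Number of nodes.
#' @param m_pa Edges per new node, `1 <= m_pa < n`.
#' @return A connected simple undirected igraph graph.
#' @examples
#' g <- generate_pa(20, 2)
#' igraph::ecount(g)  # 1 seed edge + 2 * 18 attachments = 37
#' @export
generate_pa <- function(n, m_pa) {
  n <- as.integer(n); m_pa <- as.integer(m_pa)
  if (m_pa < 1L || m_pa >= n) stop("m_pa must satisfy 1 <= m_pa < n")
  m0 <- max(m_pa, 2L)
  # seed: m0 nodes on a path (for m0 = 2, a single edge)
  el <- cbind(seq_len(m0 - 1L), seq_len(m0 - 1L) + 1L)
  deg <- integer(n)
  deg[seq_len(m0)] <- c(1L, rep(2L, max(0L, m0 - 2L)), 1L)[seq_len(m0)]
  for (v in seq.int(m0 + 1L, n)) {
    existing <- seq_len(v - 1L)
    targets <- integer(0)
    w <- deg[existing]
    for (j in seq_len(min(m_pa, v - 1L))) {
      pick <- existing[sample.int(length(existing), 1L, prob = w)]
      targets <- c(targets, pick)
      w[pick] <- 0  # distinct targets
    }
    el <- rbind(el, cbind(v, targets))
    deg[targets] <- deg[targets] + 1L
    deg[v] <- length(targets)
  }
  as_bos_graph(el, n, "PA", m_pa = m_pa)
}

#' Balanced random preference assignment
#'
#' Labels a uniformly random subset of exactly `n_alpha` nodes as alpha-types
#' (row players, preferring the alpha convention) and the rest as beta-types
#' (column players). The study default is a balanced 10/10 split on 20 nodes,
#' which maximizes the coordination conflict.
#'
#' @param n Number of nodes.
#' @param n_alpha Number of alpha-type nodes, `0 <= n_alpha <= n`.
#' @return A character vector of length `n` with entries `"alpha"`/`"beta"`.
#' @examples
#' table(assign_preferences(20))
#' @export
assign_preferences <- function(n, n_alpha = n %/% 2L) {
  n <- as.integer(n); n_alpha <- as.integer(n_alpha)
  if (n_alpha < 0L || n_alpha > n) stop("n_alpha must lie in [0, n]")
  prefs <- rep("beta", n)
  prefs[sample.int(n, n_alpha)] <- "alpha"
  prefs
}

#' Read or write a graph as GraphML or an edge list
#'
#' Thin wrappers over [igraph::write_graph()] / [igraph::read_graph()]. Edge
#' lists are whitespace-delimited with 0-based node ids.
#'
#' @param g An igraph graph.
#' @param path File path.
#' @param format `"graphml"` or `"edgelist"`.
#' @return `write_network()` returns `path` invisibly; `read_network()`
#'   returns an undirected igraph graph.
#' @export
write_network <- function(g, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  igraph::write_graph(g, path, format = format)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  g <- igraph::read_graph(path, format = format)
  igraph::as_undirected(g, mode = "collapse")
}
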