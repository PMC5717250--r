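# Independent oracles used by the unit and acceptance tests. These
# deliberately avoid the package's own code paths wherever the package result
# is the thing under test.

# Brute-force local-majority count: smallest x such that playing the
# preferred action against x coordinating neighbours weakly beats the
# alternative, evaluated through total_payoff() on a star graph.
brute_required_neighbors <- function(d, S) {
  g <- igraph::make_star(d + 1, mode = "undirected", center = 1)
  prefs <- rep("alpha", d + 1)
  for (x in 0:d) {
    actions <- c("alpha", rep("alpha", x), rep("beta", d - x))
    pay_pref <- total_payoff(1, "alpha", actions, prefs, g, S)
    pay_alt <- total_payoff(1, "beta", actions, prefs, g, S)
    if (pay_pref >= pay_alt) return(x)
  }
  d + 1L
}

# Direct evaluation of the modularity double sum with the total-degree
# normalizer, independent of igraph.
modularity_by_hand <- function(edges, membership) {
  n <- length(membership)
  A <- matrix(0, n, n)
  for (r in seq_len(nrow(edges))) {
    A[edges[r, 1], edges[r, 2]] <- A[edges[r, 1], edges[r, 2]] + 1
    A[edges[r, 2], edges[r, 1]] <- A[edges[r, 2], edges[r, 1]] + 1
  }
  k <- rowSums(A)
  two_m <- sum(k)
  same <- outer(membership, membership, "==")
  sum((A - outer(k, k) / two_m) * same) / two_m
}

# All set partitions of 1..n as a list of membership vectors (restricted
# growth strings).
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxid) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (b in seq_len(maxid + 1L))
      rec(c(prefix, b), max(maxid, b))
  }
  rec(integer(0), 0L)
  out
}

# Exact absorption probability of the 3-node path game into the all-alpha
# state, by enumerating the Markov chain on the alpha-probability grid.
# prefs = c("alpha","beta","alpha"), S fixed; neighbour lists hard-coded for
# the path 1-2-3. Returns P(absorb all-alpha | start at preferred-certainty).
path3_absorption_alpha <- function(S = 0.9, grid = 10L) {
  nb <- list(2L, c(1L, 3L), 2L)
  u_pref <- c(1, 1, 1)          # payoff per coordinating neighbour, preferred
  is_alpha <- c(TRUE, FALSE, TRUE)
  u_alpha <- ifelse(is_alpha, 1, S)
  u_beta <- ifelse(is_alpha, S, 1)
  k <- c(1, 2, 1)
  states <- as.matrix(expand.grid(p1 = 0:grid, p2 = 0:grid, p3 = 0:grid))
  ns <- nrow(states)
  idx <- function(p) p[1] * (grid + 1)^0 + p[2] * (grid + 1)^1 +
    p[3] * (grid + 1)^2 + 1L
  # per action profile: deterministic probability delta for each node
  profiles <- as.matrix(expand.grid(a1 = c(FALSE, TRUE), a2 = c(FALSE, TRUE),
                                    a3 = c(FALSE, TRUE)))
  deltas <- t(apply(profiles, 1, function(a) {
    n_alpha <- vapply(nb, function(j) sum(a[j]), numeric(1))
    pay_a <- n_alpha * u_alpha
    pay_b <- (k - n_alpha) * u_beta
    realized <- ifelse(a, pay_a, pay_b)
    counter <- ifelse(a, pay_b, pay_a)
    reinforce <- realized >= counter
    ifelse(a == reinforce, 1L, -1L)
  }))
  P <- matrix(0, ns, ns)
  for (s in seq_len(ns)) {
    p <- states[s, ]
    for (r in seq_len(nrow(profiles))) {
      a <- profiles[r, ]
      prob <- prod(ifelse(a, p / grid, 1 - p / grid))
      if (prob == 0) next
      nxt <- pmin(grid, pmax(0L, p + deltas[r, ]))
      P[s, idx(nxt)] <- P[s, idx(nxt)] + prob
    }
  }
  i_alpha <- idx(c(grid, grid, grid))
  i_beta <- idx(c(0L, 0L, 0L))
  transient <- setdiff(seq_len(ns), c(i_alpha, i_beta))
  Q <- P[transient, transient]
  b <- P[transient, i_alpha]
  x <- solve(diag(length(transient)) - Q, b)
  start <- idx(c(grid, 0L, grid))
  x[match(start, transient)]
}
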