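#' Game parameters for the networked coordination game
#'
#' The stage game is an asymmetric 2x2 coordination game: coordinating on a
#' node's preferred convention pays 1 per coordinating neighbour, coordinating
#' on the other convention pays `S` (with `0 < S < 1`), and miscoordination
#' pays 0. Play is iterated: each round every node samples an action from its
#' current mixing probability, collects payoffs against all neighbours, and
#' shifts the probability of the action it played by `step` towards the
#' myopic best response (up if the played action did at least as well as its
#' alternative, down otherwise), clipped to \eqn{[0, 1]}.
#'
#' @param S Payoff for coordinating on the non-preferred convention,
#'   `0 < S < 1` (default 0.9, the value that maximizes the dynamics).
#' @param step Probability increment per round (default 0.1; stored internally
#'   as an integer number of grid units so the probability grid stays exact).
#' @param t_min Minimum number of rounds before convergence may be declared
#'   (default 10).
#' @param t_max Maximum number of rounds (default 100).
#' @param rule `"probabilistic"` (grid dynamics above) or `"deterministic"`
#'   (probability jumps straight to 1 for the strictly better action; the
#'   played action is kept on ties).
#' @return An object of class `game_params`.
#' @examples
#' game_params(S = 0.9)
#' @export
game_params <- function(S = 0.9, step = 0.1, t_min = 10L, t_max = 100L,
                        rule = c("probabilistic", "deterministic")) {
  rule <- match.arg(rule)
  if (S <= 0 || S >= 1) stop("S must lie strictly between 0 and 1")
  if (step <= 0 || step > 1) stop("step must lie in (0, 1]")
  grid <- round(1 / step)
  if (abs(grid * step - 1) > 1e-8)
    stop("step must divide 1 exactly (e.g. 0.1, 0.05)")
  t_min <- as.integer(t_min); t_max <- as.integer(t_max)
  if (t_min > t_max) stop("t_min must not exceed t_max")
  structure(list(S = S, step = step, grid = as.integer(grid),
                 t_min = t_min, t_max = t_max, rule = rule),
            class = "game_params")
}

#' @export
print.game_params <- function(x, ...) {
  cat(sprintf("<game_params> S = %g, step = %g, rounds in [%d, %d], %s rule\n",
              x$S, x$step, x$t_min, x$t_max, x$rule))
  invisible(x)
}

#' Best-response threshold fraction
#'
#' The minimum fraction `q` of a node's neighbours that must play the node's
#' preferred convention for that convention to be a (weak) best reply:
#' playing it yields `q d` while switching yields `(1 - q) d S`, so the
#' preferred convention wins whenever `q >= S / (1 + S)`.
#'
#' @param S Off-preference coordination payoff, `0 < S <= 1`.
#' @return The threshold fraction `S / (1 + S)`.
#' @examples
#' coordination_threshold(0.9)  # 0.4737
#' coordination_threshold(0.5)  # 1/3
#' @export
coordination_threshold <- function(S) {
  if (any(S <= 0 | S > 1)) stop("S must lie in (0, 1]")
  S / (1 + S)
}

#' Neighbours required for a local majority
#'
#' The smallest integer number of coordinating neighbours `x` such that
#' playing the preferred convention against `x` of `d` neighbours weakly
#' beats playing the alternative against the remaining `d - x`:
#' `x >= (d - x) S`. Even degrees need exactly half the neighbourhood;
#' odd degrees need strictly more than half, which is the source of the
#' even-degree advantage.
#'
#' @param d Degree (vectorized), `d >= 1`.
#' @param S Off-preference coordination payoff.
#' @return Integer count(s) of required neighbours.
#' @examples
#' required_neighbors(1:8, 0.9)  # 1 1 2 2 3 3 4 4
#' @export
required_neighbors <- function(d, S) {
  if (any(d < 1)) stop("d must be >= 1")
  if (any(S <= 0 | S > 1)) stop("S must lie in (0, 1]")
  as.integer(ceiling(d * S / (1 + S) - 1e-12))
}

#' Total payoff of one node for a candidate action
#'
#' Sums the stage-game payoffs of node `i` against each neighbour: every
#' neighbour playing `action` contributes 1 if `action` is `i`'s preferred
#' convention and `S` otherwise; miscoordinating pairs contribute 0.
#'
#' @param i Node index (1-based).
#' @param action `"alpha"` or `"beta"`: the action evaluated for node `i`.
#' @param actions Character vector of all nodes' current actions.
#' @param prefs Character vector of preferences (`"alpha"`/`"beta"`).
#' @param g The igraph graph.
#' @param S Off-preference coordination payoff.
#' @return The total payoff (numeric scalar).
#' @examples
#' g <- igraph::make_star(4, mode = "undirected", center = 1)
#' total_payoff(1, "alpha", c("alpha", "alpha", "alpha", "beta"),
#'              rep("alpha", 4), g, S = 0.9)  # 2 coordinating neighbours x 1
#' @export
total_payoff <- function(i, action, actions, prefs, g, S) {
  n <- igraph::vcount(g)
  if (i < 1 || i > n) stop("node not in graph")
  nb <- as.integer(igraph::neighbors(g, i))
  n_coord <- sum(actions[nb] == action)
  u <- if (action == prefs[i]) 1 else S
  n_coord * u
}

#' One application of the probabilistic update rule
#'
#' Moves the played strategy's probability up by `step` if its realized
#' payoff was at least the counterfactual payoff of the alternative (weak
#' inequality: ties reinforce the played strategy), down by `step`
#' otherwise, clipping to \eqn{[0, 1]}. The returned value is expressed as
#' the alpha-probability regardless of which action was played.
#'
#' @param p_prev Previous alpha-probability on the step grid.
#' @param played `"alpha"` or `"beta"`, the action realized this round.
#' @param realized Payoff obtained with `played`.
#' @param counterfactual Payoff the alternative action would have obtained
#'   against the same neighbour actions.
#' @param step Probability increment.
#' @return The updated alpha-probability.
#' @examples
#' update_probability(0.5, "alpha", realized = 2, counterfactual = 0.9)  # 0.6
#' update_probability(0.5, "alpha", realized = 0, counterfactual = 0.9)  # 0.4
#' @export
update_probability <- function(p_prev, played, realized, counterfactual,
                               step = 0.1) {
  reinforced <- realized >= counterfactual
  delta <- ifelse((played == "alpha") == reinforced, step, -step)
  pmin(1, pmax(0, p_prev + delta))
}

## Internal vectorized round. State is the integer alpha-probability in grid
## units (0..grid). Returns list(p = new grid state, a = logical played-alpha,
## reinforce = logical).
step_round <- function(p_units, A, k, u_alpha, u_beta, params) {
  grid <- params$grid
  a <- stats::runif(length(p_units)) < p_units / grid
  n_alpha <- as.vector(A %*% a)
  pay_a <- n_alpha * u_alpha
  pay_b <- (k - n_alpha) * u_beta
  realized <- ifelse(a, pay_a, pay_b)
  counter <- ifelse(a, pay_b, pay_a)
  reinforce <- realized >= counter
  if (params$rule == "probabilistic") {
    delta <- ifelse(a == reinforce, 1L, -1L)
    p_new <- pmin(grid, pmax(0L, p_units + delta))
  } else {
    # jump to certainty for the strictly better action; keep played on ties
    p_new <- ifelse(pay_a > pay_b, grid,
                    ifelse(pay_b > pay_a, 0L, ifelse(a, grid, 0L)))
  }
  list(p = as.integer(p_new), a = a, reinforce = reinforce)
}

#' Advance the game state by one round
#'
#' All nodes sample an action from their current alpha-probability, payoffs
#' (realized and counterfactual) are evaluated against the same round's
#' sampled neighbour actions, and all probabilities update synchronously.
#'
#' @param state List with element `p`, the per-node alpha-probability (on the
#'   step grid), and optionally `t`, the round index.
#' @param g The igraph graph.
#' @param prefs Character preference vector.
#' @param params A [game_params()] object.
#' @return A state list with updated `p`, the sampled actions `a`
#'   (`"alpha"`/`"beta"`), and incremented `t`.
#' @export
play_round <- function(state, g, prefs, params = game_params()) {
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  k <- rowSums(A)
  is_alpha <- prefs == "alpha"
  u_alpha <- ifelse(is_alpha, 1, params$S)
  u_beta <- ifelse(is_alpha, params$S, 1)
  p_units <- as.integer(round(state$p * params$grid))
  r <- step_round(p_units, A, k, u_alpha, u_beta, params)
  list(p = r$p / params$grid,
       a = ifelse(r$a, "alpha", "beta"),
       t = (if (is.null(state$t)) 0L else state$t) + 1L)
}

## Stability of an all-0/1 state: with deterministic actions implied by p,
## does every node's played action weakly beat its alternative?
is_absorbing <- function(p_units, A, k, u_alpha, u_beta, grid) {
  if (!all(p_units == 0L | p_units == grid)) return(FALSE)
  a <- p_units == grid
  n_alpha <- as.vector(A %*% a)
  pay_a <- n_alpha * u_alpha
  pay_b <- (k - n_alpha) * u_beta
  all(ifelse(a, pay_a >= pay_b, pay_b >= pay_a))
}

#' Run one iterated game to convergence
#'
#' Starting from every node playing its preferred convention with
#' probability 1, rounds are iterated until the first round `t >= t_min` at
#' which every alpha-probability is 0 or 1 *and* no node's update would move
#' any probability (each node's realized action weakly beats its
#' alternative), or until `t_max` rounds have been played, whichever comes
#' first.
#'
#' @param g A connected igraph graph.
#' @param prefs Character preference vector (`"alpha"`/`"beta"`), one entry
#'   per node.
#' @param params A [game_params()] object.
#' @param trajectory If `TRUE`, keep the per-round alpha-probability matrix.
#' @return An object of class `bos_game`: a list with `final_p` (per-node
#'   alpha-probability), `final_action`, `preferred` (logical: final action
#'   equals own preference), `converged`, `rounds`, `proportion_alpha`,
#'   `prefs`, `params` and optionally `trajectory` (rounds x nodes matrix,
#'   row 0 = initial state).
#' @examples
#' set.seed(1)
#' g <- generate_er(20, 0.2)
#' res <- run_game(g, assign_preferences(20), game_params(S = 0.9))
#' res
#' @export
run_game <- function(g, prefs, params = game_params(), trajectory = FALSE) {
  n <- igraph::vcount(g)
  stopifnot(length(prefs) == n)
  if (!igraph::is_connected(g)) stop("g must be connected")
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  k <- rowSums(A)
  is_alpha <- prefs == "alpha"
  u_alpha <- ifelse(is_alpha, 1, params$S)
  u_beta <- ifelse(is_alpha, params$S, 1)
  grid <- params$grid
  p <- ifelse(is_alpha, grid, 0L)  # preferred option played with probability 1
  traj <- if (trajectory) list(p / grid) else NULL
  converged <- FALSE
  t <- 0L
  last_a <- is_alpha
  while (t < params$t_max) {
    r <- step_round(p, A, k, u_alpha, u_beta, params)
    p <- r$p
    last_a <- r$a
    t <- t + 1L
    if (trajectory) traj[[t + 1L]] <- p / grid
    if (t >= params$t_min &&
        is_absorbing(p, A, k, u_alpha, u_beta, grid)) {
      converged <- TRUE
      break
    }
  }
  final_p <- p / grid
  final_action <- ifelse(final_p > 0.5, "alpha",
                         ifelse(final_p < 0.5, "beta",
                                ifelse(last_a, "alpha", "beta")))
  out <- list(final_p = final_p,
              final_action = final_action,
              preferred = final_action == prefs,
              converged = converged,
              rounds = t,
              proportion_alpha = mean(final_action == "alpha"),
              prefs = prefs,
              params = params)
  if (trajectory) {
    out$trajectory <- do.call(rbind, traj)
    rownames(out$trajectory) <- seq_len(nrow(out$trajectory)) - 1L
  }
  class(out) <- "bos_game"
  out
}

#' @export
print.bos_game <- function(x, ...) {
  cat(sprintf(
    "<bos_game> %d nodes, S = %g, %s rule: %s after %d rounds\n",
    length(x$final_p), x$params$S, x$params$rule,
    if (x$converged) "converged" else "stopped (not converged)", x$rounds))
  cat(sprintf("  proportion alpha = %.3f, preferred outcome for %d/%d nodes\n",
              x$proportion_alpha, sum(x$preferred), length(x$preferred)))
  invisible(x)
}

#' @export
summary.bos_game <- function(object, ...) {
  out <- list(
    proportion_alpha = object$proportion_alpha,
    heterogeneity = heterogeneity(object$proportion_alpha),
    converged = object$converged,
    rounds = object$rounds,
    preferred_share = mean(object$preferred))
  class(out) <- "summary.bos_game"
  out
}

#' @export
print.summary.bos_game <- function(x, ...) {
  cat(sprintf(paste0(
    "proportion alpha %.3f | heterogeneity %.3f | preferred share %.3f | ",
    "%s in %d rounds\n"),
    x$proportion_alpha, x$heterogeneity, x$preferred_share,
    if (x$converged) "converged" else "not converged", x$rounds))
  invisible(x)
}

#' Plot a game trajectory
#'
#' Draws each node's alpha-probability across rounds (requires
#' `run_game(..., trajectory = TRUE)`), coloured by preference type.
#'
#' @param x A `bos_game` with a stored trajectory.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.bos_game <- function(x, ...) {
  if (is.null(x$trajectory))
    stop("re-run run_game() with trajectory = TRUE to plot")
  cols <- ifelse(x$prefs == "alpha", "#D55E00", "#0072B2")
  graphics::matplot(
    x = as.integer(rownames(x$trajectory)), y = x$trajectory,
    type = "l", lty = 1, col = cols,
    xlab = "round", ylab = "P(play alpha)", ylim = c(0, 1), ...)
  graphics::legend("right", legend = c("alpha type", "beta type"),
                   col = c("#D55E00", "#0072B2"), lty = 1, bty = "n")
  invisible(x)
}

#' Dump a stored trajectory as a tidy CSV
#'
#' One row per round and node: `round`, `node`, `p_alpha`.
#'
#' @param game A `bos_game` with a stored trajectory.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(game, path) {
  if (is.null(game$trajectory))
    stop("re-run run_game() with trajectory = TRUE first")
  tr <- game$trajectory
  df <- data.frame(
    round = rep(as.integer(rownames(tr)), ncol(tr)),
    node = rep(seq_len(ncol(tr)), each = nrow(tr)),
    p_alpha = as.vector(tr))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
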