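test_that("coordination threshold is S/(1+S) with validated input", {
  expect_equal(coordination_threshold(0.9), 0.9 / 1.9)
  expect_equal(coordination_threshold(0.5), 1 / 3)
  expect_equal(coordination_threshold(1), 0.5)
  expect_error(coordination_threshold(0), "S")
  expect_error(coordination_threshold(-1), "S")
})

test_that("required_neighbors reproduces the local-majority table", {
  expect_identical(required_neighbors(1:8, 0.9),
                   c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
  # as percentages: 100, 50, 67, 50, 60, 50, 57, 50
  pct <- round(100 * required_neighbors(1:8, 0.9) / (1:8))
  expect_identical(pct, c(100, 50, 67, 50, 60, 50, 57, 50))
  expect_equal(required_neighbors(1, 0.9), 1L)
})

test_that("required_neighbors agrees with the brute-force payoff oracle", {
  for (S in c(0.5, 0.7, 0.9)) {
    for (d in 1:12) {
      expect_equal(required_neighbors(d, S), brute_required_neighbors(d, S),
                   info = sprintf("d=%d S=%g", d, S))
    }
  }
})

test_that("total_payoff sums pairwise stage-game payoffs", {
  g <- igraph::make_star(4, mode = "undirected", center = 1)
  prefs <- c("alpha", "beta", "beta", "beta")
  actions <- c("alpha", "alpha", "alpha", "beta")
  expect_equal(total_payoff(1, "alpha", actions, prefs, g, 0.9), 2.0)
  expect_equal(total_payoff(1, "beta", actions, prefs, g, 0.9), 0.9)
  # no coordinating neighbours -> zero
  expect_equal(total_payoff(1, "beta", c("beta", rep("alpha", 3)), prefs,
                            g, 0.9), 0)
  # beta-type with 4 beta neighbours earns 4 x 1
  g5 <- igraph::make_star(5, mode = "undirected", center = 1)
  expect_equal(total_payoff(1, "beta", rep("beta", 5), rep("beta", 5),
                            g5, 0.9), 4.0)
  expect_error(total_payoff(9, "alpha", actions, prefs, g, 0.9), "node")
})

test_that("probability update moves the played strategy by one step", {
  expect_equal(update_probability(0.5, "alpha", 2.0, 0.9), 0.6)
  expect_equal(update_probability(0.5, "alpha", 0, 0.9), 0.4)
  expect_equal(update_probability(1.0, "alpha", 2.0, 0.9), 1.0)  # clipped
  expect_equal(update_probability(0, "beta", 1, 0), 0)           # clipped
  # ties reinforce the played strategy (weak inequality)
  expect_equal(update_probability(0.5, "beta", 0.9, 0.9), 0.4)
  expect_equal(update_probability(0.5, "alpha", 0.9, 0.9), 0.6)
})

test_that("first-round hand-traces follow the payoff comparison", {
  # dyad with opposed preferences: both miscoordinate and retreat to 0.9
  g2 <- igraph::make_full_graph(2)
  st <- play_round(list(p = c(1, 0)), g2, c("alpha", "beta"))
  expect_equal(st$p, c(0.9, 0.1))
  expect_equal(st$t, 1L)
  # path alpha-beta-alpha: middle node's beta-probability drops to 0.9
  g3 <- igraph::make_graph(~ 1 - 2, 2 - 3)
  st3 <- play_round(list(p = c(1, 0, 1)), g3, c("alpha", "beta", "alpha"))
  expect_equal(st3$p, c(0.9, 0.1, 0.9))
})

test_that("a homogeneous clique at certainty is a fixed point", {
  g <- igraph::make_full_graph(5)
  st <- play_round(list(p = rep(1, 5)), g, rep("alpha", 5))
  expect_equal(st$p, rep(1, 5))
  res <- run_game(g, rep("alpha", 5))
  expect_true(res$converged)
  expect_equal(res$rounds, res$params$t_min)
  expect_equal(res$proportion_alpha, 1)
})

test_that("probabilities stay on the step grid throughout the game", {
  set.seed(31)
  for (rep in 1:5) {
    g <- generate_er(12, 0.3)
    res <- run_game(g, assign_preferences(12), trajectory = TRUE)
    expect_true(all(abs(res$trajectory * 10 - round(res$trajectory * 10))
                    < 1e-12))
    expect_true(all(res$trajectory >= 0 & res$trajectory <= 1))
  }
})

test_that("convergence implies an absorbing all-0/1 state", {
  set.seed(13)
  for (rep in 1:10) {
    g <- generate_er(15, 0.25)
    prefs <- assign_preferences(15)
    res <- run_game(g, prefs)
    if (!res$converged) next
    expect_true(all(res$final_p %in% c(0, 1)))
    # every node's realized action weakly beats its alternative
    acts <- res$final_action
    ok <- vapply(seq_len(15), function(i) {
      total_payoff(i, acts[i], acts, prefs, g, 0.9) >=
        total_payoff(i, setdiff(c("alpha", "beta"), acts[i]), acts, prefs,
                     g, 0.9)
    }, logical(1))
    expect_true(all(ok))
    # and it is a fixed point of the dynamics
    st <- play_round(list(p = res$final_p), g, prefs)
    expect_equal(st$p, res$final_p)
  }
})

test_that("the dyad game absorbs at each convention equally often", {
  g <- igraph::make_full_graph(2)
  prefs <- c("alpha", "beta")
  set.seed(61)
  outcomes <- replicate(400, run_game(g, prefs)$proportion_alpha)
  expect_true(all(outcomes %in% c(0, 1)))  # always homogeneous
  expect_lt(abs(mean(outcomes) - 0.5), 4 * sqrt(0.25 / 400))
})

test_that("path game absorption matches the exact Markov-chain oracle", {
  exact <- path3_absorption_alpha(S = 0.9)
  # the lone middle node usually wins: it is reinforced as soon as one
  # neighbour flips, while each end needs the middle itself to flip
  expect_lt(exact, 0.5)
  expect_gt(exact, 0)
  g3 <- igraph::make_graph(~ 1 - 2, 2 - 3)
  prefs <- c("alpha", "beta", "alpha")
  set.seed(91)
  emp <- mean(replicate(1500, run_game(g3, prefs)$proportion_alpha == 1))
  expect_lt(abs(emp - exact), 3 * sqrt(exact * (1 - exact) / 1500) + 0.01)
})

test_that("balanced designs produce symmetric long-run outcomes", {
  set.seed(71)
  g <- generate_er(10, 0.35)
  props <- replicate(300, run_game(g, assign_preferences(10))$proportion_alpha)
  expect_lt(abs(mean(props) - 0.5), 0.1)
})

test_that("deterministic best response can cycle forever on the dyad", {
  g <- igraph::make_full_graph(2)
  res <- run_game(g, c("alpha", "beta"),
                  game_params(rule = "deterministic"))
  expect_false(res$converged)
  expect_equal(res$rounds, res$params$t_max)
})

test_that("deterministic rule converges where a strict majority exists", {
  # alpha-majority triangle: both rules settle on all-alpha
  g <- igraph::make_full_graph(3)
  set.seed(5)
  res <- run_game(g, c("alpha", "alpha", "beta"),
                  game_params(rule = "deterministic"))
  expect_true(res$converged)
  expect_equal(res$proportion_alpha, 1)
})

test_that("game parameters are validated and printed", {
  expect_error(game_params(S = 1.2), "S")
  expect_error(game_params(step = 0.3), "divide")
  expect_error(game_params(t_min = 50, t_max = 10), "t_min")
  expect_output(print(game_params()), "probabilistic")
})

test_that("trajectories dump to tidy CSV", {
  set.seed(19)
  g <- generate_er(8, 0.4)
  res <- run_game(g, assign_preferences(8), trajectory = TRUE)
  path <- tempfile(fileext = ".csv")
  write_trajectory(res, path)
  df <- read.csv(path)
  expect_named(df, c("round", "node", "p_alpha"))
  expect_equal(nrow(df), 8 * (res$rounds + 1))
  unlink(path)
})
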