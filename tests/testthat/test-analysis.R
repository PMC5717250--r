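test_that("descriptives of a single game equal the observed values", {
  cfg <- design_config(n_er = 1, n_sw = 0, n_pa = 0,
                       configs_per_network = 1, S_values = 0.9, seed = 12)
  d <- run_design(cfg)
  desc <- descriptives(d)
  expect_equal(desc$mean[desc$variable == "proportion_alpha"],
               d$games$proportion_alpha)
  expect_equal(desc$mean[desc$variable == "modularity"],
               d$networks$modularity)
  expect_equal(desc$mean[desc$variable == "preferred"],
               mean(d$nodes$preferred))
})

test_that("descriptives honour the hard bounds of each variable", {
  cfg <- design_config(n_er = 3, n_sw = 5, n_pa = 3,
                       configs_per_network = 3, S_values = 0.9, seed = 18)
  d <- run_design(cfg)
  desc <- descriptives(d)
  expect_true(all(desc$min >= -1e-9))
  bounded <- desc$variable != "modularity"
  expect_true(all(desc$max[bounded] <= 1 + 1e-9))
  expect_lte(desc$max[desc$variable == "heterogeneity"], 0.25)
})

test_that("heterogeneity-modularity correlation handles edge cases", {
  games <- data.frame(network_id = rep(1:4, each = 2), S = 0.9,
                      heterogeneity = c(1, 1, 2, 2, 3, 3, 4, 4) / 20)
  networks <- data.frame(network_id = 1:4, modularity = c(0.1, 0.2, 0.3, 0.4))
  d <- fake_design(games = games, networks = networks)
  expect_equal(het_mod_correlation(d), 1)  # perfectly linear pairs
  networks$modularity <- 0.3
  d2 <- fake_design(games = games, networks = networks)
  expect_warning(r <- het_mod_correlation(d2), "zero variance")
  expect_true(is.na(r))
  expect_error(het_mod_correlation(fake_design(games = games[1, ],
                                               networks = networks)), "two")
})

test_that("box-kernel regression is a windowed mean with NA off support", {
  # constant outcome -> constant curve
  out <- kernel_regression(runif(50), rep(1, 50), bandwidth = 0.1,
                           x_points = c(0.25, 0.5, 0.75))
  expect_equal(out$estimate, rep(1, 3))
  # window {0, 1, 1} -> 2/3
  out2 <- kernel_regression(c(0.45, 0.5, 0.55, 0.9), c(0, 1, 1, 0),
                            bandwidth = 0.1, x_points = 0.5)
  expect_equal(out2$estimate, 2 / 3)
  # empty window -> NA
  out3 <- kernel_regression(c(0, 1), c(0, 1), bandwidth = 0.05,
                            x_points = 0.5)
  expect_true(is.na(out3$estimate))
})

test_that("kernel regression is bounded and duplication-invariant", {
  set.seed(8)
  x <- runif(200)
  y <- as.numeric(x > 0.5)
  grid <- seq(0.05, 0.95, by = 0.05)
  cur <- kernel_regression(x, y, bandwidth = 0.05, x_points = grid)
  expect_true(all(cur$estimate >= 0 & cur$estimate <= 1, na.rm = TRUE))
  # duplicating every observation leaves the curve unchanged
  cur2 <- kernel_regression(c(x, x), c(y, y), bandwidth = 0.05,
                            x_points = grid)
  expect_equal(cur$estimate, cur2$estimate)
  # step outcome with a small bandwidth: low below, high above the threshold
  expect_lt(max(cur$estimate[cur$x < 0.4], na.rm = TRUE), 0.2)
  expect_gt(min(cur$estimate[cur$x > 0.6], na.rm = TRUE), 0.8)
})

test_that("ICC hits its boundary cases", {
  # identical value sets in every group: no between-network variance
  set.seed(2)
  y <- rep(rnorm(10), times = 5)
  g <- rep(1:5, each = 10)
  expect_equal(icc(y, g), 0, tolerance = 1e-6)
  # no within-network variance
  y2 <- rep(c(0.2, 0.4, 0.9), each = 7)
  g2 <- rep(1:3, each = 7)
  expect_equal(icc(y2, g2), 1)
  expect_error(icc(1:5, rep(1, 5)), "two")
})

test_that("planted linear Power models are recovered exactly", {
  set.seed(33)
  rows <- lapply(1:10, function(i) {
    cent <- node_centralities(generate_pa(20, 2))
    cbind(network_id = i, cent)
  })
  df <- do.call(rbind, rows)
  df$power <- 0.2 + 0.5 * df$degree  # noise-free planted model
  fit <- suppressWarnings(power_regression(df, S = NULL))  # perfect-fit note
  expect_equal(fit$terms, "degree")
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  # min-max scaled slope spans the observed degree range
  rng <- diff(range(df$degree))
  expect_equal(unname(coef(fit)["degree"]), 0.5 * rng, tolerance = 1e-9)
})

test_that("backward selection is monotone and reproducible", {
  cfg <- design_config(n_er = 8, n_sw = 0, n_pa = 0,
                       configs_per_network = 10, S_values = 0.9, seed = 44)
  d <- run_design(cfg)
  f1 <- power_regression(d, family = "ER", k = 4)
  f2 <- power_regression(d, family = "ER", k = 4)
  expect_identical(f1$coefficients, f2$coefficients)
  expect_lte(length(f1$terms), 15)
  main <- c("even", "degree", "eigenvector", "betweenness", "closeness")
  expect_setequal(c(f1$terms, f1$dropped),
                  c(main, utils::combn(main, 2, paste, collapse = ":")))
  expect_true(f1$icc >= 0 && f1$icc <= 1)
  expect_true(f1$r_squared >= 0 && f1$r_squared <= 1)
  # marginality: every retained interaction has its main effects retained
  inters <- grep(":", f1$terms, value = TRUE)
  for (tm in inters)
    expect_true(all(strsplit(tm, ":")[[1]] %in% f1$terms))
  # predict() reproduces the fitted values on the estimation data
  pw <- d$power[d$power$family == "ER" & d$power$S == 0.9, ]
  expect_equal(unname(predict(f1, pw)), unname(predict(f1)),
               tolerance = 1e-8)
})

test_that("kernel curve tables cover every design group", {
  cfg <- design_config(n_er = 2, n_sw = 5, n_pa = 2,
                       configs_per_network = 2, S_values = 0.9, seed = 51)
  d <- run_design(cfg)
  cur <- kernel_curves(d, "L_n", bandwidth = 0.2)
  expect_setequal(unique(cur$group),
                  c("ER", "PA", sprintf("WS p_sm=%.2f",
                                        c(0.05, 0.1, 0.15, 0.2, 0.25))))
  expect_true(all(cur$estimate >= 0 & cur$estimate <= 1, na.rm = TRUE))
})
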