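#' Descriptive statistics of the design variables
#'
#' N, mean, SD, min and max for the dependent and independent variables of a
#' design run, pooled over every game and node row in the design (restrict
#' `S` to reproduce single-payoff summaries).
#'
#' @param design A `bos_design` from [run_design()].
#' @param S Optional payoff value to filter on (default: pool all).
#' @return A data.frame with one row per variable.
#' @export
descriptives <- function(design, S = NULL) {
  stopifnot(inherits(design, "bos_design"))
  games <- design$games
  nodes <- design$nodes
  power <- design$power
  if (!is.null(S)) {
    games <- games[games$S %in% S, ]
    nodes <- nodes[nodes$S %in% S, ]
    power <- power[power$S %in% S, ]
  }
  vars <- list(
    proportion_alpha = games$proportion_alpha,
    heterogeneity = games$heterogeneity,
    preferred = as.numeric(nodes$preferred),
    power = power$power,
    eigenvector_centrality = power$eigenvector,
    betweenness_centrality = power$betweenness,
    degree_centrality = power$degree,
    same_preference_community = nodes$L_c,
    same_preference_neighbors = nodes$L_n,
    modularity = design$networks$modularity)
  out <- data.frame(
    variable = names(vars),
    n = vapply(vars, length, integer(1)),
    mean = vapply(vars, mean, numeric(1)),
    sd = vapply(vars, stats::sd, numeric(1)),
    min = vapply(vars, min, numeric(1)),
    max = vapply(vars, max, numeric(1)))
  rownames(out) <- NULL
  out
}

#' Correlation between behavioural heterogeneity and modularity
#'
#' Pearson correlation between each game's heterogeneity \eqn{h(p_\alpha)}
#' and the Walktrap modularity of the network the game was played on, pooled
#' over all families.
#'
#' @param design A `bos_design`.
#' @param S Payoff value to restrict to (default 0.9).
#' @return The Pearson correlation coefficient (NA with a warning when either
#'   variable has zero variance).
#' @export
het_mod_correlation <- function(design, S = 0.9) {
  stopifnot(inherits(design, "bos_design"))
  games <- design$games[design$games$S %in% S, ]
  if (nrow(games) < 2) stop("need at least two games")
  mod <- design$networks$modularity[match(games$network_id,
                                          design$networks$network_id)]
  if (stats::sd(mod) == 0 || stats::sd(games$heterogeneity) == 0) {
    warning("zero variance: correlation undefined")
    return(NA_real_)
  }
  stats::cor(games$heterogeneity, mod)
}

#' Box-kernel (Nadaraya-Watson) regression curve
#'
#' Locally weighted mean of `y` given `x` with a box kernel of half-width
#' `bandwidth`: at each evaluation point the estimate is the plain mean of
#' the `y` whose `x` falls within the window. Evaluation points whose window
#' is empty get `NA`.
#'
#' @param x Predictor values (e.g. the fraction of same-preference
#'   neighbours).
#' @param y Outcomes (e.g. the 0/1 `Preferred` flag).
#' @param bandwidth Window half-width on the `x` scale (default 0.05).
#' @param x_points Evaluation points (default: a grid over the range of `x`).
#' @return A data.frame with columns `x` and `estimate`.
#' @examples
#' kernel_regression(c(0, .4, .6, 1), c(0, 0, 1, 1), bandwidth = 0.25,
#'                   x_points = 0.5)
#' @export
kernel_regression <- function(x, y, bandwidth = 0.05, x_points = NULL) {
  stopifnot(bandwidth > 0, length(x) == length(y))
  if (is.null(x_points)) x_points <- seq(min(x), max(x), length.out = 101)
  # stats::ksmooth scales the box so its support is +/- 0.5 * bandwidth
  sm <- stats::ksmooth(x, as.numeric(y), kernel = "box",
                       bandwidth = 2 * bandwidth, x.points = x_points)
  data.frame(x = sm$x, estimate = sm$y)
}

#' Kernel-regression curves of Preferred against local preference fractions
#'
#' Per network family (ER, each WS rewiring level, PA), the box-kernel
#' regression of the per-node `Preferred` flag on the fraction of
#' same-preference neighbours (`L_n`) or same-preference community members
#' (`L_c`).
#'
#' @param design A `bos_design`.
#' @param predictor `"L_n"` or `"L_c"`.
#' @param bandwidth Box-kernel half-width.
#' @param S Payoff value to restrict to.
#' @return A data.frame with columns `group`, `x`, `estimate`.
#' @export
kernel_curves <- function(design, predictor = c("L_n", "L_c"),
                          bandwidth = 0.05, S = 0.9) {
  predictor <- match.arg(predictor)
  nodes <- design$nodes[design$nodes$S %in% S, ]
  grp <- design_group(design, nodes$network_id)
  do.call(rbind, lapply(split(seq_len(nrow(nodes)), grp), function(idx) {
    cur <- kernel_regression(nodes[[predictor]][idx],
                             nodes$preferred[idx], bandwidth,
                             x_points = seq(0, 1, by = 0.01))
    cbind(group = grp[idx[1]], cur)
  }))
}

## Family label with the WS rewiring level spelled out, e.g. "WS p_sm=0.05".
design_group <- function(design, network_id) {
  nets <- design$networks
  fam <- nets$family[match(network_id, nets$network_id)]
  p_sm <- nets$p_sm[match(network_id, nets$network_id)]
  ifelse(fam == "WS", sprintf("WS p_sm=%.2f", p_sm), fam)
}

#' Intraclass correlation by one-way ANOVA
#'
#' Method-of-moments estimator of the share of variance lying between groups:
#' \eqn{(MS_B - MS_W) / (MS_B + (n_0 - 1) MS_W)} with \eqn{n_0} the
#' average group size adjustment, truncated below at 0.
#'
#' @param values Numeric outcome vector.
#' @param groups Grouping vector (e.g. network id).
#' @return The ICC estimate in \eqn{[0, 1]}.
#' @export
icc <- function(values, groups) {
  groups <- as.factor(groups)
  a <- nlevels(groups)
  if (a < 2) stop("need at least two groups")
  fit <- stats::aov(values ~ groups)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  msb <- ms[1]; msw <- ms[2]
  ni <- as.numeric(table(groups))
  N <- sum(ni)
  n0 <- (N - sum(ni^2) / N) / (a - 1)
  if (is.na(msw) || msw == 0) return(1)
  max(0, (msb - msw) / (msb + (n0 - 1) * msw))
}

## Model-frame builder: Power outcome plus the five node predictors and all
## pairwise interactions in uncentered variables.
power_terms <- function() {
  main <- c("even", "degree", "eigenvector", "betweenness", "closeness")
  inter <- utils::combn(main, 2, paste, collapse = ":")
  c(main, inter)
}

power_model_matrix <- function(df, scale = c("minmax", "natural", "zscore"),
                               scaling = NULL) {
  scale <- match.arg(scale)
  main <- c("even", "degree", "eigenvector", "betweenness", "closeness")
  X <- as.matrix(df[main])
  if (is.null(scaling)) {
    scaling <- lapply(setdiff(main, "even"), function(v) {
      switch(scale,
             minmax = c(min(X[, v]), max(X[, v])),
             zscore = c(mean(X[, v]), stats::sd(X[, v])),
             natural = NULL)
    })
    names(scaling) <- setdiff(main, "even")
  }
  for (v in setdiff(main, "even")) {
    sc <- scaling[[v]]
    if (is.null(sc)) next
    if (scale == "minmax") {
      if (diff(sc) > 0) X[, v] <- (X[, v] - sc[1]) / diff(sc)
    } else if (scale == "zscore") {
      if (sc[2] > 0) X[, v] <- (X[, v] - sc[1]) / sc[2]
    }
  }
  pairs <- utils::combn(main, 2)
  inter <- apply(pairs, 2, function(p) X[, p[1]] * X[, p[2]])
  colnames(inter) <- apply(pairs, 2, paste, collapse = ":")
  out <- cbind(`(Intercept)` = 1, X, inter)
  attr(out, "scaling") <- scaling
  out
}

## Pooled k-fold cross-validated R^2 of an OLS fit on the given columns.
## Folds are fixed by the caller; aliased columns are fit as zero.
cv_r2 <- function(X, y, cols, fold) {
  pred <- numeric(length(y))
  for (f in unique(fold)) {
    test <- fold == f
    fit <- stats::lm.fit(X[!test, cols, drop = FALSE], y[!test])
    beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
    pred[test] <- X[test, cols, drop = FALSE] %*% beta
  }
  1 - sum((y - pred)^2) / sum((y - mean(y))^2)
}

#' Backward-selected OLS model of node Power
#'
#' Fits ordinary least squares of per-node Power on the even-degree dummy,
#' the four centralities and all ten pairwise interactions (uncentered), then
#' prunes terms by cross-validated backward elimination: at each pass the
#' term whose removal least reduces the k-fold cross-validated \eqn{R^2} is
#' dropped, as long as that reduction is at most `delta` (0.01); selection
#' stops when every candidate removal would cost more; removals respect
#' marginality (a main effect is only considered once no retained interaction
#' contains it). Folds are assigned by network id, so cross-validation
#' respects the clustering of nodes within networks.
#'
#' By default the four continuous centralities are min-max scaled to
#' \eqn{[0,1]} over the estimation sample, so a centrality coefficient reads
#' as the change in predicted Power from that centrality's observed minimum
#' to its maximum, and the even dummy and the Power outcome stay on the
#' probability scale. `scale = "natural"` keeps the raw normalized
#' centralities; `scale = "zscore"` standardizes them to unit variance.
#'
#' @param design A `bos_design`, or a data.frame shaped like its `power`
#'   table (columns `power`, `network_id`, `even`, `degree`, `eigenvector`,
#'   `betweenness`, `closeness`, and `family`/`p_sm` if filtering is used).
#' @param family Optional family filter (`"ER"`, `"WS"`, `"PA"`).
#' @param p_sm Optional WS rewiring-level filter.
#' @param S Payoff value to restrict to (default 0.9).
#' @param k Number of cross-validation folds (default 10, capped at the
#'   number of networks).
#' @param delta Maximum tolerated loss of cross-validated \eqn{R^2} per
#'   removal (default 0.01).
#' @param scale Predictor scaling: `"minmax"` (default), `"natural"` or
#'   `"zscore"` (see Details).
#' @param fold_seed Seed for the fold assignment of network ids.
#' @return An object of class `bos_power_fit` with components `coefficients`,
#'   `terms` (selected), `r_squared` (in-sample), `cv_r_squared`, `icc`,
#'   `dropped`, `n`, `n_networks`, `fit` (the underlying [stats::lm]) and
#'   `call` metadata.
#' @examples
#' d <- run_design(design_config(scale = 0.01, S_values = 0.9, seed = 7))
#' fit <- power_regression(d, family = "PA")
#' coef(fit)
#' @export
power_regression <- function(design, family = NULL, p_sm = NULL, S = 0.9,
                             k = 10L, delta = 0.01,
                             scale = c("minmax", "natural", "zscore"),
                             fold_seed = 1L) {
  scale <- match.arg(scale)
  df <- if (inherits(design, "bos_design")) design$power else design
  if (!is.null(S) && "S" %in% names(df)) df <- df[df$S %in% S, ]
  if (!is.null(family)) df <- df[df$family %in% family, ]
  if (!is.null(p_sm)) df <- df[!is.na(df$p_sm) & df$p_sm %in% p_sm, ]
  nets <- unique(df$network_id)
  if (length(nets) < 2) stop("need at least two networks")
  X <- power_model_matrix(df, scale = scale)
  scaling <- attr(X, "scaling")
  y <- df$power

  # drop aliased (constant / collinear) columns once, with a warning
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- setdiff(colnames(X), colnames(X)[qrX$pivot[seq_len(qrX$rank)]])
    warning("dropping aliased terms: ", paste(aliased, collapse = ", "))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  }

  k <- min(as.integer(k), length(nets))
  set.seed(fold_seed)
  net_fold <- sample(rep_len(seq_len(k), length(nets)))
  fold <- net_fold[match(df$network_id, nets)]

  terms <- setdiff(colnames(X), "(Intercept)")
  current <- cv_r2(X, y, c("(Intercept)", terms), fold)
  dropped <- character(0)
  while (length(terms) > 0) {
    # marginality: a main effect is only droppable once no retained
    # interaction contains it
    in_inter <- unique(unlist(strsplit(grep(":", terms, value = TRUE), ":")))
    droppable <- setdiff(terms, in_inter)
    if (length(droppable) == 0) break
    cand <- vapply(droppable, function(tm)
      cv_r2(X, y, c("(Intercept)", setdiff(terms, tm)), fold), numeric(1))
    best <- names(cand)[which.max(cand)]
    if (current - cand[best] <= delta) {
      dropped <- c(dropped, best)
      terms <- setdiff(terms, best)
      current <- cand[best]
    } else break
  }

  sel <- c("(Intercept)", terms)
  dat <- as.data.frame(X[, sel, drop = FALSE])[-1]
  names(dat) <- make.names(names(dat))
  dat$power <- y
  fit <- stats::lm(power ~ ., data = dat)
  coefs <- stats::coef(fit)
  names(coefs) <- sel
  out <- list(coefficients = coefs,
              terms = terms,
              r_squared = summary(fit)$r.squared,
              cv_r_squared = current,
              icc = icc(y, df$network_id),
              dropped = dropped,
              n = length(y),
              n_networks = length(nets),
              k = k, delta = delta, scale = scale, scaling = scaling,
              family = family, p_sm = p_sm, S = S,
              fit = fit, data = df)
  class(out) <- "bos_power_fit"
  out
}

#' @export
coef.bos_power_fit <- function(object, ...) object$coefficients

#' @export
print.bos_power_fit <- function(x, ...) {
  lab <- if (is.null(x$family)) "all families" else
    paste(x$family, collapse = "+")
  cat(sprintf(
    "<bos_power_fit> %s, S = %s: %d terms retained of %d candidates\n",
    lab, paste(x$S, collapse = ","), length(x$terms),
    length(x$terms) + length(x$dropped)))
  print(round(x$coefficients, 4))
  cat(sprintf("R-squared %.3f (CV %.3f), ICC %.3f, n = %d nodes / %d networks\n",
              x$r_squared, x$cv_r_squared, x$icc, x$n, x$n_networks))
  invisible(x)
}

#' @export
summary.bos_power_fit <- function(object, ...) {
  print(object)
  cat("\nUnderlying OLS fit:\n")
  print(summary(object$fit))
  invisible(object)
}

#' @export
predict.bos_power_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$fit))
  X <- power_model_matrix(newdata, scale = object$scale,
                          scaling = object$scaling)
  sel <- names(object$coefficients)
  as.vector(X[, sel, drop = FALSE] %*% object$coefficients)
}

#' Min-to-max effect of a centrality in a fitted Power model
#'
#' The average change in predicted Power when one centrality moves from its
#' observed minimum to its observed maximum while every other predictor
#' keeps its observed value. For a model whose only term in the centrality
#' is its (min-max scaled) main effect this is exactly that coefficient;
#' with retained interactions it is the average partial effect.
#'
#' @param object A `bos_power_fit`.
#' @param newdata Data on the estimation-table format; defaults to the data
#'   the model was fitted on.
#' @param variable Centrality name (default `"degree"`).
#' @return The average min-to-max effect (a probability-scale scalar).
#' @export
centrality_effect <- function(object, newdata = NULL,
                              variable = "degree") {
  stopifnot(inherits(object, "bos_power_fit"))
  if (is.null(newdata)) newdata <- object$data
  rng <- range(newdata[[variable]])
  hi <- lo <- newdata
  hi[[variable]] <- rng[2]
  lo[[variable]] <- rng[1]
  mean(predict(object, hi) - predict(object, lo))
}

#' @export
residuals.bos_power_fit <- function(object, ...) stats::residuals(object$fit)
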