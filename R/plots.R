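#' Outcome histograms of a design run
#'
#' Histograms of the converged proportion of alpha play, one panel per
#' network family (ER, each WS rewiring level, PA) plus a within-community
#' panel pooling all networks. Clustered (low `p_sm`) small worlds put most
#' of their mass in the interior, random and preferential-attachment
#' networks at the homogeneous extremes; within communities outcomes are
#' near-homogeneous everywhere.
#'
#' @param x A `bos_design`.
#' @param S Payoff value to restrict to.
#' @param ... Unused.
#' @export
plot.bos_design <- function(x, S = 0.9, ...) {
  games <- x$games[x$games$S %in% S, ]
  grp <- design_group(x, games$network_id)
  groups <- unique(grp[order(match(grp, c("ER", sort(unique(grp)))))])
  groups <- c("ER", sort(setdiff(groups, c("ER", "PA")), decreasing = TRUE),
              "PA")
  groups <- groups[groups %in% grp]
  n_panel <- length(groups) + 1L
  old <- graphics::par(mfrow = c(ceiling(n_panel / 4), 4),
                       mar = c(4, 3, 2, 1))
  on.exit(graphics::par(old))
  brk <- seq(0, 1, by = 0.1)
  for (gname in groups)
    graphics::hist(games$proportion_alpha[grp == gname], breaks = brk,
                   main = gname, xlab = "proportion alpha", col = "grey70")
  comm <- x$community_outcomes[x$community_outcomes$S %in% S, ]
  graphics::hist(comm$prop_alpha, breaks = brk,
                 main = "within communities", xlab = "proportion alpha",
                 col = "grey40")
  invisible(x)
}

#' Density of node Power by design group
#'
#' Kernel densities of per-node Power for ER, PA and each WS rewiring level.
#' Lower rewiring (stronger community structure) shifts the density right:
#' more nodes can secure their preferred convention.
#'
#' @param design A `bos_design`.
#' @param S Payoff value to restrict to.
#' @export
plot_power_density <- function(design, S = 0.9) {
  pw <- design$power[design$power$S %in% S, ]
  grp <- design_group(design, pw$network_id)
  groups <- sort(unique(grp))
  cols <- grDevices::hcl.colors(length(groups), "Dark 3")
  dens <- lapply(groups, function(gname)
    stats::density(pw$power[grp == gname], from = 0, to = 1))
  graphics::plot(NA, xlim = c(0, 1),
                 ylim = c(0, max(vapply(dens, function(d) max(d$y), 1))),
                 xlab = "node Power", ylab = "density", main = "")
  for (i in seq_along(dens)) graphics::lines(dens[[i]], col = cols[i], lwd = 2)
  graphics::legend("topleft", legend = groups, col = cols, lwd = 2, bty = "n")
  invisible(design)
}

#' Write the standard figure set of a design run
#'
#' Outcome histograms, kernel-regression panels of Preferred against the
#' local preference fractions, and Power densities, one PNG each.
#'
#' @param design A `bos_design`.
#' @param dir Output directory (created if missing).
#' @param S Payoff value to restrict to.
#' @param bandwidth Box-kernel half-width for the regression panels.
#' @return Character vector of the files written, invisibly.
#' @export
design_figures <- function(design, dir, S = 0.9, bandwidth = 0.05) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  dev_png <- function(name) {
    path <- file.path(dir, name)
    grDevices::png(path, width = 1400, height = 900, res = 120)
    path
  }
  files[1] <- dev_png("outcome_histograms.png")
  plot(design, S = S)
  grDevices::dev.off()

  files[2] <- dev_png("kernel_regression.png")
  old <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  for (pred in c("L_n", "L_c")) {
    curves <- kernel_curves(design, pred, bandwidth = bandwidth, S = S)
    groups <- unique(curves$group)
    cols <- grDevices::hcl.colors(length(groups), "Dark 3")
    graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1),
                   xlab = paste("fraction same preference,", pred),
                   ylab = "P(Preferred)")
    for (i in seq_along(groups)) {
      cur <- curves[curves$group == groups[i], ]
      graphics::lines(cur$x, cur$estimate, col = cols[i], lwd = 2)
    }
    graphics::legend("topleft", legend = groups, col = cols, lwd = 2,
                     bty = "n", cex = 0.7)
  }
  graphics::par(old)
  grDevices::dev.off()

  files[3] <- dev_png("power_density.png")
  plot_power_density(design, S = S)
  grDevices::dev.off()
  invisible(files)
}
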