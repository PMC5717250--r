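---
title: "Asymmetric coordination games on networks: model, design and measurement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Asymmetric coordination games on networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bosnet)
```

## The model

`bosnet` simulates an iterated, networked "Battle of the Sexes": every node
of a connected graph repeatedly plays an asymmetric 2x2 coordination game
against each of its neighbours, choosing one action per round for all
interactions at once. Each node intrinsically prefers one of two conventions
(call them $\alpha$ and $\beta$). Per coordinating neighbour the payoff is 1
when the pair coordinates on the node's preferred convention and
$S \in (0,1)$ when it coordinates on the other; miscoordination pays 0. So
for a node of degree $d$ facing a fraction $q$ of neighbours playing its
preferred convention, the preferred convention is a (weak) best reply iff

$$ q\,d \ge (1-q)\,d\,S \iff q \ge \frac{S}{1+S}. $$

At the default $S = 0.9$ the threshold is $0.9/1.9 \approx 0.474$: a node
with an even degree needs exactly half of its neighbours, a node with an odd
degree strictly more than half. That integer effect (`required_neighbors()`)
is the source of the *even-degree advantage* that shows up throughout the
local analysis.

### Response dynamics

Play is boundedly rational rather than equilibrium-selected. Each node $i$
carries a mixing probability $p_i^t$ of playing $\alpha$, initialised at
certainty on its preferred convention. Every round:

1. each node samples an action from its current probability;
2. realized payoffs are evaluated against the neighbours' *same-round*
   actions, along with the counterfactual payoff of the unplayed action
   against those same actions;
3. all probabilities update synchronously: the played action's probability
   moves up by 0.1 if it did at least as well as its alternative (ties
   reinforce the played action — the inequality is weak), down by 0.1
   otherwise, clipped to $[0,1]$.

Probabilities therefore live on the exact grid $\{0, 0.1, \dots, 1\}$;
internally they are stored as integer tenths so no floating-point drift can
leave the grid. A game ends at the first round $t \ge t_{\min} = 10$ in
which every probability is 0 or 1 *and* no node's update would move it
(every node's realized action weakly beats its alternative), or after
$t_{\max} = 100$ rounds. With the probabilistic rule, non-convergence is
rare; when it happens the final action is the convention with probability
above one half (at exactly one half, the last sampled action) and the game
is flagged unconverged. A `rule = "deterministic"` variant jumps straight to
certainty on the strictly better reply (keeping the played action on ties);
it reproduces the same qualitative picture but can cycle forever — the
opposed dyad alternates eternally — which is why the probabilistic rule is
the default.

Two readings of the update rule were open: whether actions are sampled
every round or the modal action is played, and whether the two conventions'
probabilities are tracked separately. We sample every round (the rule is
explicitly a probability of *playing*), and we track the $\alpha$
probability with the $\beta$ probability as its complement, which the
one-step update preserves.

## The synthetic experiment

All data are simulated; the generator *is* the study design:

| parameter | default | meaning |
|---|---|---|
| $n$ | 20 | nodes per network |
| $n_\alpha$ | 10 | $\alpha$-preferring nodes (balanced split maximizes conflict) |
| $p_{er}$ | 0.2 | ER edge probability (expected degree 3.8) |
| $k_{ws}$ | 4 | WS ring-lattice degree |
| $p_{sm}$ | 0.05–0.25 | WS rewiring probability (5 levels, 200 networks each) |
| $m_{pa}$ | 2 | PA edges per arriving node (density matched to ER) |
| $S$ | 0.9, 0.7, 0.5 | off-preference payoff; 0.9 maximizes the dynamics |
| networks | 1000 per family | |
| configurations | 100 per network | random balanced preference assignments |

Graphs must be connected; ER and WS draws are rejected and resampled until
connected (budget 10,000 attempts), PA is connected by construction.
Watts-Strogatz rewiring is the textbook dialect: each lattice edge
independently redirects its far endpoint to a uniform non-duplicate,
non-self target. The PA seed is $m_0 = 2$ nodes joined by an edge; the
first arrival attaches to both, so a 20-node network always has exactly
37 edges.

Two generator choices deserve a note. The WS lattice degree is set to 4
(two neighbours *per side*): a $k=2$ ring has zero clustering and half the
target density, while $k=4$ matches the ER/PA density (mean degree
3.8/3.7) and produces the high-clustering small worlds the design needs;
the pure lattice's clustering is exactly $3(k-2)/(4(k-1)) = 0.5$. And the
1000 WS networks are split equally, 200 per rewiring level — the only
symmetric allocation.

Randomness is controlled by a single root seed from which per-network,
per-configuration and per-game child seeds are drawn up front; game seeds
are reused across $S$ values so payoff comparisons are paired, and all
seeds are recorded in the output tables. `design_config(scale = )`
rescales network and configuration counts proportionally for desk runs
without touching any estimator definition.

### What the generator does and does not emulate

The generator reproduces the study conditions exactly (sizes, densities,
balanced preferences, payoffs). It does not emulate real social networks:
degree distributions are bounded at $n = 20$, there is no homophily in the
preference assignment, no weighted or dynamic ties, and no behavioural
noise beyond the sampling in the update rule. Passing tests therefore show
that the pipeline reproduces the *model's* behaviour under these
conditions, not that real groups behave this way.

## Measurement

* **Global outcomes.** Per game: the proportion $p_\alpha$ of nodes playing
  $\alpha$ at the end, and its heterogeneity $h(p_\alpha) = p_\alpha(1 -
  p_\alpha)$ (the Bernoulli variance; 0 at homogeneity, 0.25 at an even
  split, symmetric under relabelling).
* **Communities.** Walktrap (random-walk agglomeration, walk length 4 — the
  algorithm's usual default; lengths 2–6 move the mean modularity by less
  than 0.005 on these graphs) with the merge tree cut at maximal Newman
  modularity $Q$, normalized by total degree $2m$. The definition is
  sometimes written with a node-count normalizer; only the $2m$ form is
  internally consistent and matches the observed range of $Q$ on these
  designs (roughly 0.11–0.52), so that is what `graph_modularity()`
  computes (via igraph, hand-verified on closed-form cases: two bridged
  triangles split at the bridge give $Q = 5/14$, a dyad with singleton
  communities $-1/2$).
* **Local conditions.** $L^n_i$: the fraction of $i$'s neighbours sharing
  $i$'s preference. $L^c_i$: the fraction of the *other* members of $i$'s
  community sharing $i$'s preference (singleton community: 1 by
  convention). The focal node is excluded from $L^c$ because the inclusive
  variant inflates the statistic's level (mean ~0.58 vs ~0.47) and
  variance structure in a way the rest of the analysis contradicts.
* **Position.** Normalized degree $k_i/(n-1)$; eigenvector centrality
  scaled to maximum 1; betweenness normalized by $(n-1)(n-2)/2$; closeness
  $(n-1)/\sum_j d(i,j)$; and the even-degree dummy.
* **Preferred / Power.** Per game, `Preferred` flags nodes whose final
  action equals their own preference; `Power` is a node's mean of
  `Preferred` over a network's preference configurations — the positional
  advantage measure. Estimates stabilize around 100 configurations, which
  is why Power-based statistics are computed from 100-configuration runs
  even in scaled-down replications: Power's granularity is
  1/configurations, and the resulting measurement noise attenuates any
  $R^2$ computed on it (at 30 configurations the ER model's $R^2$ drops
  from ~0.65 to ~0.47 for that reason alone).

## The statistical layer

`descriptives()` reproduces the pooled summary table;
`het_mod_correlation()` the Pearson correlation between per-game
heterogeneity and network modularity; `kernel_curves()` the box-kernel
(Nadaraya–Watson) regressions of `Preferred` on $L^n$ and $L^c$. The box
kernel has half-width 0.05 on the fraction scale by default: the curves
have a sharp tipping point at the local-majority threshold, which a
half-width of 0.5 (an almost global window on $[0,1]$ predictors) would
smear away entirely, so a literal bandwidth of 0.5 is only sensible as a
full-width-in-some-other-convention reading; the parameter is exposed.

`power_regression()` is the positional model: OLS of Power on the
even-degree dummy, the four centralities, and all ten pairwise interactions
(uncentered), pruned by cross-validated backward elimination — repeatedly
drop the term whose removal least reduces the 10-fold cross-validated
$R^2$, as long as that costs at most 0.01, respecting marginality (a main
effect only becomes droppable once no retained interaction contains it).
Folds are assigned by *network*, not node, so the cross-validation honours
the clustering of observations. Continuous centralities are min–max scaled
to $[0,1]$ over the estimation sample by default, so a coefficient reads
as the change in predicted Power from the observed minimum to maximum of
that centrality while the even dummy and the outcome stay on the
probability scale; natural and z-score scalings are available. Collinear
(aliased) columns are dropped once, with a warning, before selection.
`icc()` reports the between-network share of Power variance from the
one-way ANOVA method-of-moments estimator, truncated at zero; it stays
below ~0.1 on all families, which is why the models are plain OLS rather
than mixed-effects fits.

## Problem sizes and reproducibility

The full design (3000 networks x 100 configurations x 3 payoff levels) is
feasible but unnecessary for verification. The package's own checks use a
1/10-scale replication (100 ER + 20 x 5 WS + 100 PA networks, 30
configurations, $S = 0.9$) for the global statistics, single-family runs of
100–200 networks at 100 configurations for the Power-based statistics, and a
full-count structural replication (3000 networks, no games) for mean
modularity, whose Monte-Carlo error at 300 networks is the same order as
the margin being tested. `scripts/acceptance.R` re-runs exactly these
computations from scratch at a caller-chosen seed.

A worked desk-scale example:

```{r example, eval = FALSE}
d <- run_design(design_config(scale = 0.1, S_values = 0.9, seed = 1))
descriptives(d)
het_mod_correlation(d)
power_regression(d, family = "PA")
plot(d)               # outcome histograms per family and rewiring level
plot_power_density(d) # Power densities
```

## Numerical choices and degenerate inputs

* Probabilities are integer tenths internally; `step` must divide 1 exactly.
* Ties in the payoff comparison reinforce the played action (weak
  inequality), including the zero-zero tie of a fully miscoordinated node.
* `required_neighbors()` uses an epsilon-guarded ceiling so exact-integer
  thresholds (even degrees) are not pushed up by floating-point error.
* Rejection sampling failures (overly sparse parameter choices) raise an
  error naming the budget rather than looping forever.
* `het_mod_correlation()` on zero-variance modularity returns `NA` with a
  warning; empty kernel windows yield `NA` at those evaluation points;
  `power_regression()` needs at least two networks and drops aliased
  columns.
* Vertex-transitive graphs (rings, cliques) give every node the same Power
  up to Monte-Carlo error, and a balanced design's long-run mean proportion
  of $\alpha$ is 0.5 by label symmetry — both are exploited as tests.

## Known limitations

* Equilibrium *selection* is only characterized distributionally; absorbing
  states are sensitive to the sampled path, and small instances can be
  enumerated exactly (the test suite solves the three-node path's Markov
  chain in closed form — the lone middle player wins most of the time,
  which simple majority intuition gets wrong).
* Within-community outcomes are predominantly but not exclusively
  homogeneous under these generators: roughly three quarters of
  community-level outcomes are fully one-convention at $S = 0.9$; the
  strict >80% reading of "almost exclusively homogeneous" is not met, and
  the corresponding check is deliberately left failing rather than
  weakened.
* The pooled heterogeneity–modularity correlation lands near 0.42–0.43
  under the textbook WS rewiring dialect, at the lower edge of the
  reference band around 0.49; the igraph whole-edge rewiring dialect was
  evaluated and moves the correlation further down, so the textbook
  dialect is retained.
* No alternative update rules (imitation, Fermi), no weighted graphs, no
  alternative community detectors, and no mixed-effects modelling beyond
  the ICC diagnostic — all deliberate scope bounds.
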