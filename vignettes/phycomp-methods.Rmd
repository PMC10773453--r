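---
title: "Models and methods in phycomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in phycomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phycomp)
```

phycomp implements a core set of phylogenetic comparative methods: Markov
models of discrete character evolution and their state-space expansions,
stochastic character mapping, continuous-trait models built on Brownian
motion, and simple diversification analyses. This vignette is the package's
own account of the models, the numerical choices behind them, and what the
test suite does and does not establish.

## Discrete characters: the extended Mk model

A discrete trait with $k$ levels evolves along the tree as a continuous-time
Markov chain with instantaneous rate matrix $Q$ ($k \times k$, off-diagonals
$\ge 0$, rows summing to zero). Model structure is declared through an
integer *design matrix*: zeros forbid transitions, and equal positive
integers tie rates into shared classes. `build_design()` provides the three
classical templates — ER (one rate), SYM (one rate per unordered pair), ARD
(one rate per ordered pair, numbered row by row) — and accepts arbitrary
templates such as irreversible models.

The likelihood is computed by Felsenstein's pruning algorithm in compiled
code, with per-edge transition matrices $e^{Qt}$ obtained by a
scaling-and-squaring Padé matrix exponential. Partial likelihoods are
rescaled at every internal node and the log factors accumulated, so
underflow is controlled on trees of hundreds of tips even at high rates.
Zero-length edges carry the identity transition matrix. Ambiguous or missing
tip states place partial likelihood 1 on every allowed level.

Three root priors are available: flat (`"equal"`, the default — this is the
convention under which the package reproduces published binary-trait model
tables), a user-fixed vector, and the FitzJohn nuisance prior, which weights
each root state by its share of the root's conditional likelihood.

`fit_mk()` maximizes the likelihood over the log-rates inside the box
$[10^{-12}, 10^3]$, starting from a parsimony-informed guess (Fitch changes
per unit total branch length) and, when `nstarts > 1`, from exponential
perturbations of it. Expanded-state models default to 10 restarts because
their likelihood surfaces are multimodal; the plain Mk model defaults to 1.
`compare_models()` turns any set of fits into a table of AIC values and
Akaike weights $w_i = e^{-\Delta_i/2} / \sum_j e^{-\Delta_j/2}$.

### Ancestral states

`ancr()` computes marginal state probabilities with the standard two-pass
algorithm (postorder conditional likelihoods, then a preorder "outside"
pass), or the single most probable joint assignment by max-product dynamic
programming with traceback. Ties in the joint reconstruction are broken
toward the lowest state index so the output is deterministic. Given a model
table, marginals are model-averaged with Akaike weights; all fits must share
the tree and state space.

### State-space expansions

*Polymorphic characters.* Observed conditions such as `"forest+fringe"` are
treated as genuine states in an expanded space in which transitions gain or
lose one level at a time; a change between two monomorphic states must pass
through their polymorphic intermediate. The unordered space contains every
non-empty subset of the levels (even unobserved ones, matching the printed
design conventions of the field); the ordered space only contiguous runs of
the stated order — the unique choice consistent with the published
parameter counts (12 ordered vs 18 unordered free ARD rates for three
levels). The `"transient"` model has exactly two classes: one shared by all
polymorphism-gaining moves and one by all polymorphism-losing moves.
Condition strings are canonicalized, so `"a+b"` and `"b+a"` are one state.

*Hidden rates.* Each observed level is split into `ncat` rate categories
labelled with trailing stars (`O`, `O*`, ...). In the full model, observed
changes happen between equal categories and category changes between
adjacent categories of one level. In the *umbral* variant, observed-state
change is only possible from (and to) the first, labile category; starred
categories are inert. Tip states spread their likelihood over all hidden
categories of the observed level. With `ncat = 1` the model collapses
exactly to the plain ARD Mk model, which the tests assert.

## Stochastic character mapping

`sample_maps()` draws full character histories consistent with the tips:
the root state is drawn from prior $\times$ conditional likelihood, node
states follow by preorder conditional sampling given the sampled parent,
and each edge's path is then simulated conditioned on its endpoints —
forward rejection sampling with a cap of 1000 attempts per edge, falling
back to uniformization (jump counts drawn from the endpoint-conditioned
Poisson mixture, states filled in by forward-backward sampling, virtual
jumps collapsed). The reference literature does not specify the path
sampler; this combination is standard practice and is validated against the
marginal reconstructions: node-state frequencies across maps converge to
`ancr()` marginals, a property the acceptance suite checks at 10,000 maps.

Passing a model table samples the generating model for each replicate in
proportion to its Akaike weight, which integrates model-selection
uncertainty into the mapped histories. Each replicate's model choice is
recorded in the returned object for auditability.

Summaries: `summarize_maps()` (node-state frequencies, mean change counts),
`change_density()` (the distribution of per-type change counts, with 95%
HPD intervals computed as the shortest contiguous interval of the empirical
sample — not a kernel density), `density_map()` (per-edge posterior
probability of the second state on an edge-proportional grid: grid point
$i$ sits a fraction $i/\mathrm{res}$ along the edge), and `ltt_by_state()`
(lineage counts per mapped state through time; at every instant the state
counts sum to the plain lineage-through-time curve).

## Continuous traits

Under Brownian motion with rate $\sigma^2$ and root state $a$, tip values
are multivariate normal with covariance $\sigma^2 C$, where $C_{ij}$ is the
shared root-to-MRCA path length (`phylo_vcv()`).

*Signal.* Blomberg's $K$ is the ratio of observed to Brownian-expected
values of $\mathrm{MSE}_0/\mathrm{MSE}$, with the phylogenetic mean
estimated by GLS; its permutation test shuffles trait values across tips
and counts, with the plus-one convention, permutations reaching the
observed $K$ (the convention is not fixed in the literature; tests allow
$1/\mathrm{nperm}$ slack). Pagel's $\lambda$ multiplies the off-diagonal
entries of $C$; it is estimated by profile maximum likelihood on
$[0, \lambda_{\max}]$, where $\lambda_{\max}$ is the largest value keeping
$C(\lambda)$ positive definite, found by bisection (the bound is not stated
in the literature; for ultrametric trees it slightly exceeds 1). The
likelihood-ratio test against $\lambda = 0$ uses $\chi^2_1$, which
reproduces the published p-values.

*Ancestral states.* `fast_anc()` returns the conditional-normal (GLS)
estimates: the root takes the phylogenetic mean
$(\mathbf{1}'C^{-1}\mathbf{1})^{-1}\mathbf{1}'C^{-1}x$ and every other node
its conditional expectation given the tips — numerically identical to
re-rooting the tree at the node and taking the phylogenetic mean, which the
tests verify directly. `anc_bayes()` samples $\sigma^2$, the root and all
node states by Metropolis-Hastings with one-parameter-at-a-time Gaussian
random-walk proposals cycled in order ($\sigma^2$ reflected at zero).
Defaults mirror the conventional control settings: $\sigma^2$ initialized
at the mean squared phylogenetically independent contrast, states at the
phylogenetic mean, prior $N(1000, 10^6)$ on $\sigma^2$ and $N(0, 10^3)$ on
node states, proposal variances $\sigma^2_{\mathrm{init}}/100$, sampling
every 100 generations including generation 0 (so `ngen/sample + 1` rows),
and a 20% burn-in in `summary()`. With these diffuse priors the posterior
means track the ML states; the proposal default favours acceptance rates
around 0.8–0.9 on typical data, which the tests bound away from 0 and 1.

## Multivariate and rate-heterogeneous models

*Multi-regime bivariate Brownian motion* (`evolvcv_lite()`). With regimes
mapped on the tree, the stacked trait vector is normal with covariance
$\sum_r R_r \otimes C_r$, where $C_r$ holds the time spent in regime $r$ on
shared root-to-MRCA paths. The model hierarchy constrains the per-regime
rate/covariance matrices $R_r$: (1) everything common; (2) regime rates,
common correlation; (3) common rates, regime correlations; (4) free.
Rates are optimized on the log scale and correlations through `tanh`, which
keeps every $R_r$ positive semidefinite; root means are profiled by GLS.
Parameter counts for two traits and two regimes are 5/7/6/8.

*Variable-rate Brownian motion* (`multirate_bm()`). The trait follows
Brownian motion whose rate itself evolves by geometric Brownian motion.
The penalized objective is the data log-likelihood, with every edge length
scaled by that edge's rate, plus $\lambda_{\mathrm{pen}}$ times the
Brownian log-density of the node log-rates on the tree (the rate process
has no separate scale — it is absorbed by the penalty coefficient). The
edge rate is the *logarithmic mean* of the rates at its two ends,
$(\sigma^2_p - \sigma^2_c)/(\ln \sigma^2_p - \ln \sigma^2_c)$: for a rate
varying log-linearly along the edge this is the exact time average, it is
consistent with the geometric-BM rate model, and it reproduces the
published penalized likelihood for the primate example; the cruder
arithmetic mean does not. Both likelihood terms are evaluated by $O(n)$
postorder peeling, and the $2n-1$ log-rates are optimized by L-BFGS-B from
the single-rate ML start. As $\lambda_{\mathrm{pen}} \to \infty$ the fitted
rates collapse to the single-rate ML estimate (asserted at $10^6$).

*Phylogenetic PCA* (`phyl_pca()`). Traits are centred on their GLS
phylogenetic means and the $C^{-1}$-weighted covariance (or correlation) is
eigen-decomposed. In correlation mode, loadings are trait-component
correlations (all in $[-1, 1]$); score covariance, weighted by $C^{-1}$, is
diagonal with the squared singular values. Component signs are arbitrary;
tests compare absolute values. On a star tree the procedure reduces to
ordinary PCA.

## Diversification

`ltt_curve()` counts reconstructed lineages at every internal node height.
`gamma_test()` computes the standardized internode-interval statistic,
which is approximately standard normal for a completely sampled pure-birth
tree; the two-tailed p is $2\Phi(-|\gamma|)$.

The MCCR test (`mccr_test()`) calibrates $\gamma$ under incomplete
sampling: each replicate simulates a pure-birth tree with
$\mathrm{round}(n_{\mathrm{obs}}/\rho)$ tips (rounding to nearest), prunes
random tips back to $n_{\mathrm{obs}}$, and records $\gamma$; the p-value
is twice the smaller empirical tail with the plus-one convention, capped
at 1.

`fit_bd()` maximizes the reconstructed-process likelihood with sampling
fraction $\rho$: writing $r = b - d$ and
$D(t) = \rho b + (b(1-\rho) - d)e^{-rt}$, each non-crown branching time
contributes $b\,\rho r^2 e^{-rt}/D(t)^2$, the crown age enters squared, the
likelihood is conditioned on the crown age and survival of both crown
lineages, and the $(n-1)!$ labelled-histories constant is included. This
conditioning was selected by validating against the published fits of the
liolaemid tree (both birth-death and Yule rates and log-likelihoods
reproduce to print precision); the alternative (unconditioned) form does
not. Optimization runs over $(\log r, \mathrm{logit}(d/b))$ to avoid the
characteristic likelihood ridge. `fit_yule()` is the same likelihood
constrained to $d = 0$; the exported likelihood closures agree along that
boundary, as the tests assert.

## The tree simulator and synthetic data

`sim_bd_tree()` is a Gillespie simulation with exponential waiting times
starting from **two crown lineages** (so a pure-birth tree at time $t$ has
$2e^{bt}$ expected tips). When stopping at a tip count, the present is
placed at the end of one additional waiting time after the target count is
first reached — just before the next event would occur — so the final
inter-event interval is properly represented; without it, $\gamma$ would be
biased on simulated trees. Conditioning on survival is by re-simulation.
These choices make the simulator suitable as the null generator for the
MCCR test and for the $\gamma$ and Blomberg-$K$ calibration checks.

`make_fixture()` wraps the simulators into a deterministic generator of
plain-text fixtures (Newick, SIMMAP, trait CSVs, and a JSON truth file).
Its defaults — 50-tip pure-birth trees, a binary equal-rates character with
$q = 0.5$, a unit-rate Brownian trait — are chosen so that one fixture
exercises every module at desk scale. The generator emulates clean,
complete, ultrametric data; it does not emulate topological error,
measurement noise in tip states, fossil tips, or non-ultrametric trees, so
green tests establish correctness of the algorithms under their model
assumptions, not robustness of inference on messy empirical data.

## Problem sizes and tolerances in the test suite

Simulation-based checks run at sizes chosen to keep the whole suite
desk-scale while leaving Monte-Carlo error well inside the asserted bands:
500 replicates of 100-tip trees for the Brownian calibration of $K$ and for
the $\gamma$ null moments; 10,000 stochastic maps on a 20-tip fixture for
the map-frequency/marginal cross-check (3 binomial standard errors); 10-12
replicates for rate-recovery checks, asserted on medians. Likelihood
reproductions of published analyses are asserted at print precision
(|Δ logL| ≤ 0.01-0.05); optimizer-dependent rate estimates at 1-2%.
Nesting inequalities allow an optimizer tolerance of $10^{-4}$ to
$10^{-6}$.

## Known limitations

- Trees must be rooted and bifurcating-or-multifurcating with branch
  lengths; NEXUS input, unrooted trees, and reticulation are out of scope.
- `evolvcv_lite()` handles exactly two traits (the published model
  hierarchy); more traits require the general multi-regime machinery that
  this package does not implement.
- The hidden-rates and polymorphic models are weakly identified on small
  trees; multiple restarts reduce, but cannot eliminate, the risk of local
  optima, and rate estimates on likelihood ridges can differ between runs
  at identical log-likelihood.
- `multirate_bm()` leaves the choice of $\lambda_{\mathrm{pen}}$ to the
  user; no cross-validation is provided.
- The birth-death likelihood assumes uniform (missing-at-random) incomplete
  sampling through $\rho$; clade-biased sampling is not modelled.
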