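---
title: "Weighted threshold contagion: model, master equations, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted threshold contagion: model, master equations, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`wtcascade` implements a monotone binary-state threshold process on
undirected weighted networks. Each node is susceptible or infected;
infection is permanent. A node of degree $k$ has strength
$q_k = \sum_{j=1}^{k} w_{ij}$ and partial strength $q_m$, the same sum
restricted to its currently infected neighbours. In one asynchronous
update a susceptible node adopts spontaneously with probability $p$, or
else adopts if and only if

$$q_m \ge \varphi\, q_k, \qquad 0 < \varphi < 1 .$$

With $p > 0$ and no initial seed, spontaneous adopters accumulate at a
roughly linear rate until the density of infected nodes $\rho(t)$ reaches
a tipping region, after which a system-wide cascade unfolds. The speed of
that cascade is summarised by $t_a$, the first time $\rho$ reaches a
target (0.75 by default), and by the relative time
$t_r = [t_a(0,\varphi) - t_a(\sigma,\varphi)]/t_a(0,\varphi)$ against the
unweighted process at the same threshold.

Substrates are configuration-model networks: a prescribed degree sequence
wired maximally at random (stub matching followed by degree-preserving
edge switches, via igraph), with edge weights assigned i.i.d. and
independently of topology. Three weight families are provided:

* **bimodal** — strong weight $w_1 = \mu + \sigma\sqrt{(1-\delta)/\delta}$
  with probability $\delta$, weak weight
  $w_2 = \mu - \sigma\sqrt{\delta/(1-\delta)}$ otherwise. $\sigma$
  interpolates between the unweighted network ($\sigma = 0$) and the
  *diluted* network ($\sigma = \mu\sqrt{(1-\delta)/\delta}$, where
  $w_2 = 0$ and weak ties carry no influence);
* **lognormal** — parameterised by the mean $\mu$ and standard deviation
  $\sigma$ of the *weight itself* (the underlying normal parameters are
  solved analytically), since those are the quantities a practitioner
  controls when matching an empirical weight distribution;
* **empirical** — a weight multiset, optionally passed through the
  mean-preserving affine map $w' = \mu + \alpha(w - \mu)$, which keeps
  the shape and mean of the distribution while scaling its standard
  deviation to $\alpha\sigma$. Signed edge lists (trust/distrust ties)
  are mapped onto the bimodal family by reading $+$ as strong and $-$ as
  weak, with $\delta$ measured from the data.

# Approximate master equations

For analysis the weight distribution is discretised into $n$ types
$\mathbf{w} = (w_1, \dots, w_n)$. A node is classified by its per-type
degree vector $\mathbf{k}$ and per-type infected-neighbour vector
$\mathbf{m}$ ($0 \le m_j \le k_j$), with strengths
$q_\mathbf{k} = \mathbf{k}\cdot\mathbf{w}$ and
$q_\mathbf{m} = \mathbf{m}\cdot\mathbf{w}$. The stepwise infection rate is

$$F_{\mathbf{k},\mathbf{m}} =
  \begin{cases} p & q_\mathbf{m} < \varphi q_\mathbf{k} \\
                1 & q_\mathbf{m} \ge \varphi q_\mathbf{k} \end{cases}$$

for nodes that receive influence, and $F = p$ for nodes that cannot be
influenced (degree 0, or zero strength in the diluted limit — see
*Degenerate inputs* below). Because weights are assigned independently of
topology, the conditional distribution of $\mathbf{k}$ given $k$ is
multinomial with the per-link type probabilities; this is exactly what the
generator realises, so the analytic and simulated ensembles match by
construction.

The class fractions $s_{\mathbf{k},\mathbf{m}}(t)$ and
$i_{\mathbf{k},\mathbf{m}}(t)$ evolve by loss $F s$ (own adoption) plus
per-type flux terms with neighbour-infection rates $\beta^s_j$,
$\beta^i_j$: a susceptible node moves from $(\mathbf{k},\mathbf{m})$ to
$(\mathbf{k},\mathbf{m}+e_j)$ when one of its $k_j - m_j$ susceptible
$j$-neighbours adopts. Only susceptible nodes change state, so both rates
are averages of $F$ over susceptible classes, weighted by how such a node
is reached:

* $\beta^s_j$: across an S–S edge, weight $\propto (k_j - m_j)\,
  s_{\mathbf{k},\mathbf{m}}$;
* $\beta^i_j$: across an S–I edge, weight $\propto m_j\,
  s_{\mathbf{k},\mathbf{m}}$.

The $\beta^i$ closure matters only for the infected-side bookkeeping (the
bulk/surface observables below); $\rho(t)$ is driven entirely by the
susceptible side. Empty categories (zero denominators, e.g. no infected
mass at $t=0$) yield rate 0 by convention, which affects only the startup
instant.

The initial condition places all susceptible mass at $\mathbf{m} = 0$
(an infinitesimal random seed), i.e. $(\boldsymbol{\nu}, \rho) = (0, 0)$
in reduced coordinates.

## The reduced system

Because $F$ is stepwise, the full system collapses exactly to $n + 1$
equations in $\nu_j(t)$ — the probability that the neighbour across a
$j$-type edge of a susceptible node is infected — and $\rho(t)$:

$$\dot\nu_j = g_j(\boldsymbol{\nu}, t) - \nu_j, \qquad
  \dot\rho = h(\boldsymbol{\nu}, t) - \rho,$$

where $g_j$ and $h$ are sums over threshold-satisfying classes of products
of binomial factors $B_{k_j,m_j}(\nu_j) = \binom{k_j}{m_j} \nu_j^{m_j}
(1-\nu_j)^{k_j-m_j}$, $g_j$ carrying the size-bias factor $k_j / z_j$ and
one reduced binomial $B_{k_j-1,m_j}(\nu_j)$ (the focal edge's endpoint is
susceptible by construction), and
$f_t = 1 - (1-p)e^{-pt}$ accounting for cumulative spontaneous adoption.
The binomial factors are evaluated at the per-type $\nu_j$, the closure
consistent with the per-type flux structure. The package integrates both
forms; their $\rho(t)$ agree to below $10^{-4}$ on the benchmark (in
practice to $\sim 10^{-8}$), which is also the package's strongest internal
consistency check, since the two solvers share no rate code. A further
independent check integrates the classic unweighted ($n = 1$) dynamic
threshold model written directly with `dbinom` and matches it to the
reduced solver.

## Bulk and surface observables

The per-type fractions of edges joining two infected nodes ($E^{II}_j$,
the cascade bulk) and a susceptible to an infected node ($E^{SI}_j$, the
cascade surface) are ratios of $m_j$-weighted class sums over $i$ and $s$
respectively; each family sums to 1. In the symmetric unweighted case
($\sigma = 0$, $\delta = 0.5$, $n = 2$) both equal $1/2$ at all times;
with heterogeneous weights strong ties enter the bulk early (single strong
neighbours trip the threshold first) and weak ties accumulate on the
surface. The Monte Carlo engine tracks the same quantities by direct edge
counting, maintained incrementally as nodes flip.

## Phase boundaries

Setting the threshold rule to equality gives
$\varphi = \mathbf{m}\cdot\mathbf{w} / \mathbf{k}\cdot\mathbf{w}$. For
bimodal weights this is a rational function of $\sigma$ for each class
$(\mathbf{k}, \mathbf{m})$ — a curve in the $(\sigma, \varphi)$ plane
across which that class flips between adopting (rate 1) and non-adopting
(rate $p$). `enumerate_boundaries()` lists all curves of a degree class
intersecting a window, merging classes whose curves coincide as rational
functions (compared by cross-multiplied coefficients). The suite verifies
exhaustively for $k = 7$ that `infection_rate_F()` flips across every
curve, tying the combinatorial and dynamical views together.

# Monte Carlo implementation

One sweep is $N$ single-node updates; each update draws a node uniformly
*with replacement* and advances time by $1/N$. (Random-permutation
updating is the main alternative; both have the same mean-field limit, and
with-replacement is the conventional asynchronous scheme, so it is the
one implemented.) Within an update, spontaneous adoption is attempted
first; if it fails, the threshold rule is checked. Partial strengths are
maintained incrementally — infecting a node pushes its edge weights to its
susceptible neighbours — so each update is $O(1)$ amortised and the loop is
implemented in C++ (Rcpp), using R's RNG so that `set.seed()` governs
every replicate. Runs stop at `t_max`, at a target density `rho_stop`, or
— for $p = 0$ — at the frozen state where no susceptible node can still
adopt (checked once per sweep). Every stochastic operation in the package
takes an explicit integer seed, and identical seeds give identical output
on any platform.

Floating-point ties at the threshold are resolved as adoption with a
relative tolerance of $10^{-12} q_k$, so that configurations which satisfy
the rule exactly in real arithmetic (e.g. $q_m = 0.3$ vs
$\varphi q_k = (1/3) \times 0.9$) adopt despite rounding.

# Numerical choices

* **Integration.** `deSolve::ode` (lsoda/lsodar), `rtol = 1e-8`,
  `atol = 1e-10`, dense output on the Monte Carlo sampling grid (0.1
  sweeps by default); root-finding stops a run early at a requested
  density. Class-mass conservation (the per-$\mathbf{k}$ sum of $s$ and
  $i$) holds to $\sim 10^{-15}$; $\rho$ is clamped to $[0,1]$ against
  solver rounding at startup.
* **Degenerate inputs.** Nodes with $q_k = 0$ (isolated nodes, or
  all-weak nodes in the diluted limit $w_2 = 0$): the rule
  $q_m \ge \varphi q_k$ would hold vacuously at $\mathbf{m} = 0$, turning
  uninfluenceable nodes into instant adopters. They are instead treated
  as receiving no influence — spontaneous adoption only — in both
  engines, consistent with reading zero-weight ties as functionally
  absent. In-memory networks therefore admit weight 0 (the diluted
  limit); the file reader rejects non-positive weights, since a stored
  zero weight is almost certainly an authoring error.
* **Degree support.** Heavy-tailed degree distributions are truncated for
  the AME class expansion where the cumulative probability exceeds
  $1 - 10^{-6}$, bounding the class count; the truncation is
  renormalised.
* **Power-law cutoff.** The truncated power-law sampler defaults to
  $k_{\max} = 1000$; with $\tau = 2.5$, $k_{\min} = 2$ this gives an
  analytic mean degree of 4.54, the realised average degree of the
  scale-free ensembles this generator is meant to emulate. Both cutoffs
  are configurable. Sampled sequences with odd sum have their last entry
  resampled until parity is restored (bounded retries, seeded).
* **Signed-network import.** Duplicate undirected pairs with conflicting
  signs are resolved by a seeded random choice; self-loops are dropped;
  single-sign inputs are rejected ($\delta$ must lie strictly inside
  $(0,1)$ for a bimodal map).
* **$t_r$ references.** A sweep computes the $\sigma = 0$ reference with
  the same engine, the same network size, and (for Monte Carlo) the same
  replicate seed set as the weighted cells, so that topology realisations
  are shared and the difference estimate has lower variance.

# What the generator emulates — and what it does not

The synthetic ensembles reproduce the study conditions under which the
model's behaviour is established: $k$-regular ($k = 7$) and truncated
power-law ($\tau = 2.5$, $k_{\min} = 2$) configuration models of
$N = 10^4$ nodes, bimodal ($\mu = 1$, $\delta = 0.5$ symmetric;
$\mu = 3$, $\delta = 0.2$ skewed) and lognormal ($\mu = 1$) weights,
spontaneous rate $p = 2\times10^{-4}$, cascade target $\rho = 0.75$, and
25 Monte Carlo realisations per parameter cell. Weights are i.i.d. and
independent of topology. Real weighted networks additionally carry
degree–weight correlations (strong ties between low-degree pairs and vice
versa), communities, clustering, and degree correlations — none of which
the configuration model reproduces. Passing tests therefore demonstrate
the weight-heterogeneity mechanisms (non-monotonic cascade speed, bulk/
surface tie asymmetry, skewness-driven partial cascades) on maximally
random substrates, not quantitative predictions for any particular
empirical network; on real data the same mechanisms operate but the
$(\sigma,\varphi)$ phase structure is deformed by the correlations above.

## The partial-cascade scenario

Skewed bimodal weights ($\delta = 0.2$, $\mu = 3$) with large $\sigma$
drive a characteristic two-stage pattern: sparse strong ties ignite and
exhaust an early cascade over the strong-tie percolation cluster, after
which spreading continues only via spontaneous and rare weak-tie
adoptions, leaving $\rho$ on a long plateau below the cascade target — a
*partial cascade*. The packaged scenario uses $\varphi = 0.25$ (the
benchmark threshold), $\sigma = 5.5$ (about 92% of the diluted limit
$\sigma_{\max} = 6$, keeping $w_2 > 0$), and a 300-sweep window, a few
times the unweighted emergence time ($t_a \approx 118$), so the unweighted
run completes comfortably while the heterogeneous run stalls near
$\rho \approx 0.74$. Both engines agree on the plateau level.

# Problem sizes and runtimes

The test suite runs the full AME on the $k = 7$, $n = 2$ benchmark (120
classes, 240 ODEs) to $t = 50$, reduced-system sweeps to a few thousand
sweeps, and Monte Carlo at $N = 10^4$ with up to 25 replicates per
parameter cell; small-system oracle checks use exhaustive fixed-point
iteration on networks of up to 10 nodes. These sizes keep the entire
suite at a few minutes on one core while leaving Monte Carlo standard
errors well below the 5% agreement margin used in the MC-versus-AME
checks.

# Known limitations

* The AME assumes locally tree-like structure; on clustered or assortative
  networks it remains an approximation even as $N \to \infty$.
* Weight–degree correlations are deliberately out of scope for both the
  generator and the master equations.
* Only monotone dynamics is implemented; the class machinery would carry
  over to recovery dynamics, but rates, tests and reductions here assume
  permanent infection.
* The full-AME class count grows combinatorially in the number of weight
  types $n$ and the degree support; in practice $n \le 3$ with moderate
  degrees is comfortable, and the reduced system should be preferred
  whenever only $\rho(t)$ and $\nu(t)$ are needed.
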