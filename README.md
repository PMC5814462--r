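# wtcascade

Threshold-driven contagion on weighted networks: Monte Carlo simulation,
approximate master equations (AMEs), and combinatorial phase boundaries.

## The problem

Many cascading phenomena — social contagion, neural firing, epidemic
processes with dose thresholds — are modelled as *threshold dynamics*: a
node flips from susceptible to infected once the stimulus arriving from its
infected neighbours exceeds a fraction of the total stimulus it can
receive. Classic treatments assume unweighted networks, where every
neighbour counts equally. Real interaction networks are weighted, and tie
strength determines how much each neighbour contributes towards the
threshold. `wtcascade` is a toolkit for studying how *weight heterogeneity*
reshapes the speed and extent of such cascades, for modellers working on
complex contagion, spreading processes, and binary-state dynamics on
networks.

## The model

On an undirected weighted network, each node has strength
`q_k(i) = sum_j w_ij` (summed weight of its `k` incident edges) and partial
strength `q_m(i)` (the same sum restricted to its `m` infected
neighbours). A susceptible node becomes infected

* spontaneously with probability `p` per asynchronous update, or
* deterministically as soon as `q_m >= phi * q_k`, with a uniform
  threshold `0 < phi < 1`.

Infection is permanent (monotone dynamics). Weights are drawn i.i.d. from a
distribution `P(w)`; the package provides the bimodal family with mean
`mu`, standard deviation `sigma` and strong-tie fraction `delta`
(`w1 = mu + sigma*sqrt((1-delta)/delta)`, `w2 = mu -
sigma*sqrt(delta/(1-delta))`), lognormal weights parameterised by `(mu,
sigma)` of the weight itself, and empirical weight sets with a
mean-preserving contraction `w' = mu + alpha*(w - mu)` that scales `sigma`
without changing the distribution's shape. Sigma interpolates from the
unweighted network (`sigma = 0`) to the diluted one (`w2 = 0`), and signed
edge lists map onto the bimodal family (`+` strong, `-` weak).

Analytically, nodes are grouped into classes by a per-weight-type degree
vector **k** and infected-neighbour vector **m**; the class fractions
`s_(k,m)`, `i_(k,m)` obey approximate master equations whose stepwise
infection rate (`p` below threshold, 1 at or above) admits an exact
reduction to `n + 1` ODEs in the per-type neighbour-infection
probabilities `nu_j` and the infected density `rho`. Setting the threshold
rule to equality, `phi = (m . w)/(k . w)`, yields closed-form boundary
curves in the `(sigma, phi)` plane along which individual classes switch
between adopting and non-adopting, explaining the observed accelerations
and decelerations combinatorially.

The package's observables are the cascade emergence time `t_a` (first time
`rho` reaches 0.75), the relative time
`t_r = (t_a(0, phi) - t_a(sigma, phi)) / t_a(0, phi)`, and the per-type
bulk/surface edge fractions `E^II`, `E^SI` of the infected cluster.

## Worked example

The benchmark ensemble is a 7-regular configuration-model network with
bimodal weights (`mu = 1`, `delta = 0.5`) and spontaneous rate
`p = 2e-4`. Sweeping `sigma` at fixed `phi = 0.25` with the deterministic
AME engine:

```r
library(wtcascade)
dspec <- degree_spec("regular", N = 10000, k = 7)
parameter_sweep(dspec, sigma_values = c(0.3, 0.7), phi_values = 0.25,
                engine = "ame")
#>   sigma  phi       t_a partial        t_r
#> 1   0.0 0.25 114.35874   FALSE  0.0000000
#> 2   0.3 0.25 148.27947   FALSE -0.2966168
#> 3   0.7 0.25  54.64236   FALSE  0.5221846
```

The dependence on weight heterogeneity is non-monotonic: mild
heterogeneity (`sigma = 0.3`) *slows* the cascade by ~30% relative to the
unweighted network (`t_r < 0`), while strong heterogeneity (`sigma = 0.7`)
*accelerates* it (`t_r > 0`), because single strong neighbours then push
many node classes over the threshold. A matching stochastic simulation:

```r
net <- generate_network(dspec,
                        weight_scheme("bimodal", mu = 1, sigma = 0.7,
                                      delta = 0.5), seed = 1)
net
#> weighted_network: 10000 nodes, 35000 edges
#>   weight: mean 1.001, sd 0.7, range [0.3, 1.7]
#>   types: 1:17514 2:17486
ser <- run_mc(net, sim_config(phi = 0.25, p = 2e-4, t_max = 200,
                              rho_stop = 0.8, seed = 1))
absolute_time(ser, 0.75)
#> [1] 59.55361
```

One Monte Carlo realisation crosses 75% infection at `t_a = 59.6` sweeps,
consistent with the AME prediction of 54.6 (single-run fluctuations are a
few sweeps at this size). `ser$E_II` and `ser$E_SI` record how strong ties
crowd the bulk of the infected cluster while weak ties dominate its
surface; `enumerate_boundaries(7)` returns the combinatorial class
boundaries that organise the `(sigma, phi)` plane.

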