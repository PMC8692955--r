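# cpfnet — central-place foraging networks and information transmission

`cpfnet` is an R package for simulating how hunter–gatherer-style
**central-place foraging** (CPF) shapes social networks and their capacity
to transmit information. It is aimed at behavioural ecologists and
cultural-evolution modellers who want a fast, fully seeded implementation
of the foraging → co-location → network → contagion pipeline.

## The model in brief

Foraging units live on a unit square with `n_patches` patches whose
integer resource contents follow a truncated power law
*P(k) ∝ k<sup>−β</sup>*, k = 1, …, k<sub>max</sub>. Each unit has a home
patch *p<sub>h</sub>* and radius *r*. When its current patch is exhausted
it either

* **forages**: moves to the in-radius patch minimising the cost/gain
  ratio *d<sub>hj</sub>/k<sub>j</sub>* (distance from home over remaining
  content), or
* **relocates**: when the best ratio outside the radius beats the best
  inside, moves its home to the patch minimising
  *d<sub>hh′</sub>/k<sub>h′</sub>* subject to *d<sub>hh′</sub> ≥ 2r* (no
  home-range overlap).

Each unit depletes its patch by one unit per time-step; patches never
regenerate. Two units ending a step on the same patch add one unit of
weight to their network tie. *r = 0* reproduces point-to-point foraging
(no central place); *r = 1* makes relocation impossible in the unit
square, so units stay tethered.

On the emergent weighted networks the package computes **weighted global
and local efficiency** (mean inverse shortest-path length, edge lengths
*ℓ = w<sub>max</sub>/w*, so both lie in [0, 1]), Louvain **subgroup
structure**, and runs **simple and complex contagion**: an uninformed
unit adopts with probability Σw·d / Σw (simple) or its square (complex).

## Worked example

```r
library(cpfnet)

env <- build_environment(beta = 2.5, n_patches = 50000, seed = 1)
sim <- run_simulation(env, n_units = 100, radius = 0.1, n_steps = 100, seed = 2)
sim
#> Central-place foraging simulation
#>   units: 100   radius: 0.1   steps: 100   beta: 2.5
#>   network: 468 edges, total tie weight 24287
#> Mobility: n_r = 1.11 (d_r = 0.262), n_f = 7.22 (d_f = 0.0418)

global_efficiency(sim$network)
#> [1] 0.06300269
local_efficiency(sim$network)
#> [1] 0.3593515
subgroup_summary(sim$network)
#> Subgroups: 23 components, 26 communities (3 in largest component)
```

Here 100 foraging units on an intermediate-heterogeneity landscape
(β = 2.5) with radius 0.1 formed 468 weighted ties over 100 steps. Each
unit made on average 1.1 residential moves of mean length 0.26 and 7.2
foraging moves of mean length 0.04; this particular landscape produced a
fragmented network (23 components), with modest global efficiency —
replicate landscapes vary widely, which is why conditions are summarised
over 50 replicates. Scale up with:

```r
sw <- run_sweep(betas = c(1.5, 2.5, 3.5, 4.5), radii = c(0, 0.01, 0.1),
                populations = 100, reps = 10, base_seed = 1)
sw$conditions          # means with 95% CIs per condition
make_figures(sw, "figures")
```

Contagion on a network:

```r
ct <- run_contagion(sim$network, "simple", n_steps = 5000, n_runs = 50, seed = 3)
time_to_fraction(ct, 0.75)
```

A thin command-line front end (`inst/cli/cpf.R`) exposes `simulate`,
`contagion` and `sweep` subcommands over the same functions.

## Package layout

* `R/environment.R` — power-law landscapes, depletion
* `R/foraging.R` — movement rules, compiled + reference engines,
  mobility summaries
* `R/netmetrics.R` — weighted efficiencies, components, Louvain subgroups
* `R/contagion.R` — simple/complex contagion, spread-time statistics
* `R/experiments.R` — factorial sweeps, seeding, figures
* `R/fixtures.R` — hand-checkable micro-environments and toy graphs
* `vignettes/central-place-foraging-networks.Rmd` — model, assumptions,
  design decisions, limitations
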