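---
title: "Central-place foraging, emergent interaction networks, and information transmission"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Central-place foraging, emergent interaction networks, and information transmission}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpfnet)
```

## The model

`cpfnet` simulates central-place foraging (CPF) — the hunter–gatherer
pattern of exploiting a radius around a residential base and periodically
moving that base — and asks what the resulting co-location networks imply
for the spread of information.

The world is the unit square holding `n_patches` resource patches placed
i.i.d. uniformly at random. Patch $i$ starts with an integer resource
content $k_i \ge 1$ drawn from a truncated power law
$P(k) \propto k^{-\beta}$ on $k = 1, \dots, k_{max}$. The exponent
$\beta$ couples abundance and heterogeneity: near $\beta = 1.5$ a few
enormously rich patches dominate; by $\beta = 4.5$ nearly every patch
holds a single unit of food. Each time-step, every foraging unit on a
patch removes one unit of its content; patches never regenerate.

Each agent is a *foraging unit* — a nuclear family moving as one — with a
home patch $p_h$ and a foraging radius $r$. The movement rule fires only
when the unit's current patch is exhausted:

* **Foraging move**: go to the patch $p_j$ with food within $r$ of home
  minimising the cost/gain ratio $d_{hj}/k_j$ ($d_{hj}$ measured from the
  home, not the current location).
* **Residential move**: when the best ratio *outside* the radius beats
  the best ratio inside (local quality has diminished relative to the
  rest of the environment), relocate the home to the patch minimising
  $d_{hh'}/k_{h'}$ subject to the no-overlap constraint
  $d_{hh'} \ge 2r$.

$r = 0$ degenerates to point-to-point foraging (every move is a global
$d/k$ argmin; no foraging moves are ever logged), and $r = 1$ makes
relocation geometrically impossible in the unit square ($2r = 2$ exceeds
the diameter $\sqrt 2$), so those units stay tethered to their original
home — the two reference regimes the CPF conditions are compared against.

Whenever two units end a time-step on the same patch, the tie between
them gains one unit of weight. The cumulative weighted graph after the
run is the interaction network.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `beta` | 2.5 | resource-distribution exponent (dimensionless) |
| `n_patches` | 50 000 | patches on the unit square |
| `k_max` | 10 000 | truncation of the resource distribution (units of food) |
| `radius` | — | foraging radius, unit-square distance; grid 0, 0.001, 0.01, 0.1, 1 |
| `n_units` | — | foraging units; grid 50, 100, 200 |
| `n_steps` | 100 | time-steps per run |
| reps | 50 | replicate landscapes per condition |

The defaults are the study conditions; `run_sweep()` exposes all of them.
`k_max` deserves a note: the power law is normalised by
$C = 1/\sum_{k \ge 1} k^{-\beta}$, i.e. unbounded support, and we truncate
only to make exact inverse-CDF sampling possible. The cap of 10 000 leaves
the low-order moments essentially unchanged for $\beta \ge 1.5$. The
extreme upper tail (the single richest patch on a landscape) does shape
the dynamics at small radii, because relocations chase globally
outstanding patches; this is the faithful consequence of the stated
distribution rather than a tunable of the model.

## Design choices in corners the rules leave open

* **Update order.** Within a step, units whose patch is exhausted decide
  and move; depletion and co-location are applied *after* all moves. A
  unit's decision depends only on the environment and its own home, so
  the iteration order of agents within a step has no observable effect;
  we iterate in fixed id order.
* **Tie-breaking.** All argmins break ties toward the lowest patch id.
  With continuous random positions ties have measure zero; the rule
  exists so hand-built fixtures are deterministic.
* **Relocation feasibility.** If the trigger fires but no patch with
  food lies at $d \ge 2r$, the unit stays and keeps foraging inside its
  radius, idling in place if the radius is fully exhausted.
* **Concurrent depletion.** $n$ co-located units remove $n$ units of
  content per step (floored at zero).
* **Initial placement.** Units start on uniformly random patches; the
  starting patch is the initial home. Shared homes need no special
  mechanic — co-residence emerges because identical rules from identical
  homes produce identical moves.
* **Move distances.** The logged distance of a foraging move is the
  displacement actually travelled (previous location to target); the
  selection ratio uses distance from home. Residential distance is
  home-to-new-home.

## Network measures

Global efficiency is the mean inverse shortest-path length over ordered
pairs,
$$E = \frac{1}{n(n-1)} \sum_{i \neq j} d_{ij}^{-1},$$
with disconnected pairs contributing zero. To use the co-location counts
as weights we convert weight to length as $\ell_{ij} = w_{max}/w_{ij}$,
so the strongest observed tie has unit length, $E \in [0,1]$, and both
efficiencies are invariant to rescaling all weights (equivalently, to the
total observation time). This normalisation is our reconstruction of a
weighted Latora–Marchiori measure; other conventions (e.g. $\ell = 1/w$
without normalisation) change the absolute numbers, which is the main
caveat when comparing efficiency values across studies. Local efficiency
averages, over nodes, the global efficiency of each node's
neighbour-induced subgraph, normalised by the *full* network's $w_{max}$.

Subgroups ("bands") come from weighted Louvain modularity maximisation.
Louvain is randomised, so `subgroup_summary()` reports the modal
community count over 10 seeded restarts; components come from plain
connectivity. "Connected communities" counts the communities represented
in the largest component — the model's higher level of social
organisation.

## Contagion

`run_contagion()` seeds one uniformly random unit and updates
synchronously: an uninformed unit adopts at $t+1$ with probability equal
to the informed-weighted fraction of its ties (simple contagion) or the
square of that fraction (complex contagion, behaviours needing social
reinforcement). Squaring a number in $[0,1]$ never increases it, so
complex spread is stochastically slower on any fixed network — a property
the test suite asserts. Updates are synchronous because the adoption
probabilities are defined from the state at $t$; this also makes results
independent of any agent ordering. Runs that never reach a target
fraction within the step budget are excluded from the mean time and
reported as censored counts — with spread times whose standard deviations
rival their means, censoring at the maximum would bias the mean upward
badly.

Once the informed set saturates the seed's connected component the run is
completed analytically, which keeps the nominal 5000-step budget cheap.

## What the generator emulates — and what it does not

The synthetic landscapes reproduce the study conditions: i.i.d. uniform
patch positions, i.i.d. power-law contents, no regeneration, no spatial
autocorrelation, no seasonality, and omniscient agents with zero
within-step travel cost. Real foraging landscapes are spatially
autocorrelated and periodic, and real foragers have imperfect, memory-
shaped knowledge; passing tests on these landscapes therefore validates
the *mechanism* (movement rules → network structure → transmission
capacity), not any claim about a particular empirical landscape.

## Numerical and scale choices

The step loop is compiled (Rcpp); a replicate at full scale (50 000
patches, 100 units, 100 steps) takes on the order of a second, so the
published 50-replicate protocol is run as-is by `scripts/acceptance.R`
and the acceptance tests. The qualitative β-peak check uses 10
replicates per condition and the population-size check 6, sizes at which
the orderings of interest are stable across seeds. Property tests run on
1000–2000-patch landscapes, where a plain-R reference engine can mirror
the compiled core exactly; the two engines are asserted equal
move-for-move. The efficiency pipeline is cross-checked against a
Floyd–Warshall brute force to 1e-12 on random graphs.

Seeds: every random object (landscape, placement, Louvain restarts,
contagion) draws from a stream derived via a 31-bit hash of a base seed
plus labels (`derive_seed()`), so any replicate of any condition can be
regenerated in isolation.

## Known limitations

* The weighted-efficiency normalisation is a reconstruction (above);
  absolute efficiency values are sensitive to it, orderings much less so.
* At small radii the heavy upper tail of the untruncated-in-spirit
  resource distribution makes residential moves chase distant, extremely
  rich patches, which lengthens mean relocation distances and
  interconnects subgroups more than a capped distribution would. We keep
  the stated distribution; analyses that want a bounded tail can pass a
  smaller `k_max`. Population-size effects are sensitive to the same
  tail: once co-residence on outstanding patches saturates, adding units
  attaches weakly tied satellites, so mean local efficiency can fall
  rather than rise with population size at most radii (the acceptance
  test computes this trend).
* Louvain community counts on near-degenerate modularity landscapes can
  vary between restarts; the modal count stabilises but is not a proof
  of optimality (the test suite brute-forces optimality only on a
  10-node fixture).
* The contagion model has no recovery, forgetting or competing traits,
  and the threshold (deterministic) complex-contagion variant is out of
  scope.

## A worked example

```{r example, eval = FALSE}
env <- build_environment(beta = 2.5, n_patches = 50000, seed = 1)
sim <- run_simulation(env, n_units = 100, radius = 0.1, n_steps = 100,
                      seed = 2)
summary(sim)

ct <- run_contagion(sim$network, "simple", seed = 3)
time_to_fraction(ct, 0.75)
```

`run_sweep()` scales this to the full factorial design and
`make_figures()` renders the standard panels (efficiency versus β per
radius, the mobility scatter, efficiency versus population size, and
contagion trajectory bands).
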