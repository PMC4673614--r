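---
title: "An agent-based game model of avascular tumor growth: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An agent-based game model of avascular tumor growth: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumorgame)
```

## The model

`tumorgame` simulates the avascular stage of tumor growth — the phase in
which a colony is fed purely by diffusion from the surrounding tissue —
on a 2-D square lattice of `L × L` grids. Each grid can host many cells.
Three coupled processes drive the dynamics, advanced once per cell cycle
$\tau$ (the time unit; the grid spacing is the length unit):

**Nutrient.** A single generic nutrient field $\phi \in [0, 1]$ obeys a
reaction–diffusion equation,
$$\partial_t \phi = D \nabla^2 \phi - k\, N_T\, \phi,$$
where $N_T$ is the grid's living-cell count. The surrounding vasculature
holds $\phi = 1$ on the four lattice edges (Dirichlet boundaries). The
equation is integrated with an explicit 5-point finite-difference scheme,
`n_sub` substeps of length $\tau/\mathtt{n\_sub}$ per cycle with $N_T$
frozen, subject to the stability bound $D\,\Delta t \le 1/4$. The field is
clamped to $[0,1]$ and the boundary reset after each substep. The sink
proportional to $\phi$ keeps the field non-negative naturally; a constant
per-cell sink $-k N_T$ (clamped) is available via
`consumption_form = "constant"`.

**Extracellular matrix.** Each grid carries an ECM density
$\rho_{ecm} \in [0,1]$, initialised i.i.d. uniform. A cell may only be
*placed* in a grid whose ECM is exactly zero, and each living cell
degrades the ECM by $\gamma$ per cycle. The degradation footprint is the
cell's own grid **and its 8 Moore neighbours** (`degrade_neighbors =
TRUE`). This footprint is a deliberate model choice: under a literal
own-grid-only rule, with a continuous uniform initial field, no
neighbouring grid ever reaches exactly zero and the colony can never
leave its founding grid. The literal mode is retained as a switch and
covered by a regression test. Degradation clamps to exact zero so the
strict-zero placement predicate is well defined in floating point.

**Phenotypes and the game.** Living cells carry one of two behavioural
phenotypes — proliferative or invasive — and become necrotic
(permanently inert) when their grid's nutrient falls strictly below
$\phi_c$. Each cycle every surviving cell draws a fresh fate from
$$P_p = \mathrm{clamp}\Big(1 - e^{-(\phi/(N_T \theta_p))^2} + \Delta_p\Big),
\qquad
P_i = \mathrm{clamp}\Big(e^{-(\phi/(N_T \theta_i))^2} + \Delta_i\Big),$$
normalised to sum to one. The base terms depend on the nutrient *per
cell* $\phi/N_T$: division is favoured when the local supply per cell is
generous, migration when it is poor. The increments $\Delta_p, \Delta_i$
are the game: a payoff matrix (`payoff_matrix()`) scores encounters with
the living cells of the interaction neighbourhood (same grid, excluding
the focal cell, plus the 8 Moore neighbours, phenotypes frozen at the
previous round). By convention `standard_payoffs()` stores an
*inhibition* $\alpha_{pp} \ge 0$ between proliferative cells as
$a_{pp} = -\alpha_{pp}$ and an *enhancement* $\beta_{ii} \ge 0$ between
invasive cells as $b_{ii} = +\beta_{ii}$; the cross terms default to
zero. Payoffs are averaged over the interaction partners by default
(`payoff_aggregation = "mean"`), which keeps the increments bounded as
density grows; `"sum"` is available. If both clamped probabilities are
zero the cell holds for the cycle (the 0/0 normalisation is undefined,
and a hold is the only neutral reading).

**Synchronous update.** One call to `step_world()` applies, in order:
ECM degradation, nutrient renewal, necrosis, fate draws, and the
synchronous placement of all divisions and migrations. A daughter cell is
placed in the current grid or an ECM-free Moore neighbour; a migrant
must move to an ECM-free neighbour and stays put when none exists. Both
choose their destination lexicographically: fewest total cells (necrotic
included), then highest nutrient, then uniformly at random among ties.
All comparisons use start-of-step values, so several arrivals can land in
one grid within a cycle. A simulation stops when the colony touches the
lattice boundary or after `t_max` cycles.

## Parameters, units and defaults

| parameter | meaning | unit | default |
|---|---|---|---|
| `L` | lattice side | grids | 401 |
| `t_max` | run length | $\tau$ | 200 |
| `D` | nutrient diffusivity | grid$^2/\tau$ | 1.0 |
| `k` | consumption per living cell | $1/\tau$ | 0.3 |
| `phi_c` | necrosis threshold | — | 0.25 |
| `theta_p`, `theta_i` | fate-probability shape | — | 0.3 |
| `gamma` | ECM degradation per cell | $1/\tau$ | 0.4 |
| `n_sub` | diffusion substeps | — | 8 |
| $\alpha_{pp}$, $\beta_{ii}$ | payoff magnitudes | — | 0.1 |

The rate constants are not published as a complete set, so they are
calibration constants of this implementation. They were fixed, once, so
that the default configuration reproduces the qualitative reference
phenomenology of avascular growth under $\alpha_{pp} = \beta_{ii} = 0.1$:

* necrotic cells first appear after about ten cell cycles (the colony is
  then a few grids wide and the diffusive resupply, with decay length
  $\sqrt{D/(k N_T)}$, no longer reaches its centre);
* the necrotic fraction rises to a plateau near 0.9 while the invasive
  fraction peaks early and ends below 0.1;
* the mean front radius $r(t)$ grows linearly ($R^2 > 0.99$) with
  velocity $v \approx 1.1$ grids/$\tau$, so an $L = 401$ lattice is
  filled in almost exactly 200 cycles;
* the global surface roughness grows as $R(t) \sim t^\beta$ with
  $\beta \approx 1$.

Two couplings discovered during calibration are worth recording. First,
the threshold $\phi_c$ must sit well above the deep-starvation level: the
migration rule follows the nutrient gradient outward, so with a very low
threshold cells evacuate a starving core before dying and no necrotic
core forms. Second, the near-linear growth of $R(t)$ is carried by the
direction dependence of the ballistic front (diagonal Moore steps cover
$\sqrt 2$ grids), which requires ECM clearing not to be rate-limiting —
hence $\gamma$ of order 0.4 rather than a much smaller value.

## Morphometrics

All statistics use polar coordinates about the founder's central grid.

* `front_profile()` divides the circle into `n_angular_bins` (default
  360) equal bins and records the *maximum* living-cell radius per bin;
  empty bins are excluded, not interpolated. The per-bin maximum rather
  than a connected-contour trace is a deliberate, simpler front
  definition; arc-length weighting is not applied.
* `surface_roughness()` is the population (1/N) standard deviation of
  the per-bin front radii — the spread of the front, 0 for a perfect
  circle up to a discretisation floor of about half a grid.
* `mean_front_radius()` and `fit_slope()` give the radial growth
  velocity $v$; `fit_loglog_exponent()` gives the roughening exponent.
  Fits discard `burn_in` (default 30) early cycles during which the
  colony is too small for front statistics.
* `radial_distribution()` computes, per quadrant sector, the probability
  density $g(r)$ of the living cells' radial distance
  ($g(r) = n(r)/(N_s \Delta r)$, $\sum g \Delta r = 1$, bin width
  default 2 grids). A per-sector density was chosen over an
  annulus-area-normalised variant because it integrates to one by
  construction and directly shows the outward-moving, sector-dependent
  peak that makes the growing asymmetry visible.

## Reproducibility and numerics

A run is fully determined by its `sim_config()`: `initialize_world()`
seeds R's global RNG from `config$seed`, draws the ECM field then the
nutrient field, and the engine consumes draws in a fixed documented
order (per cycle: proliferative-class then invasive-class fate binomials
over living grids in row-major order, then placement draws in the same
order). Two runs with equal configurations are bit-identical; sweep
trials derive unique seeds deterministically from the base seed and grid
indices. Ties in the placement rule compare counts and nutrient values
exactly (no tolerance): count ties are common and broken uniformly at
random; nutrient ties essentially only occur on symmetric hand-built
fixtures.

The engine is count-based: grids store per-phenotype counts rather than
agent identities, and fate draws are binomial per (grid, phenotype
class). This is distributionally equivalent to a literal per-agent
scheduler — the test suite checks the equivalence against an independent
per-agent reference implementation on a 9×9 lattice over 2000 seeded
replicates — and is what makes 401×401×200 runs take seconds rather than
hours in pure R.

## What the simulations do and do not show

The model emulates: diffusion-limited nutrient supply with a stable
vascular boundary, a rough radially symmetric colony with a necrotic
core and a thin living rim, Gompertz-like deceleration of total growth,
linear front advance, and kinetic roughening of the growth front. It
does not emulate: mutation or genotype–phenotype maps, reversible
quiescence (cells below threshold die outright; the model treats
"quiescent" and "necrotic" as one absorbing state), structured or
regenerating ECM, chemotaxis beyond the local placement rule,
anisotropic diffusion, or three dimensions. Passing tests on this model
therefore say nothing about those mechanisms in real tumors; the package
is a laboratory for the phenotype-game question, not a clinical
predictor.

Two quantitative reference behaviours are known not to be reproduced by
this reconstruction, and the test suite records them as expected
failures rather than hiding them. First, the per-grid necrotic count
distribution: the deposition density behind the front equals (shell
width × living density × division rate) / front velocity, which with a
sparse living shell (median 1–2 cells per occupied grid) yields a
geometric-like distribution with mode 1, not a bell-shaped distribution
peaked at ten or more; packing the shell hard enough to shift the mode
also pushes the median living count above the reference bound, so the
two cannot hold simultaneously here. Second, the direction of the
payoff effect on the roughness velocity: because fates are normalised to
sum to one, every front cell acts exactly once per cycle and divisions
and migrations advance the front equally, so $\langle v_r \rangle$ is
set by lattice anisotropy and is insensitive to the payoff corners (the
measured corner difference is below its standard error, at both payoff
aggregations).

## Problem sizes used in the checks

The acceptance analysis runs the full `fig2_default` geometry
(`L = 401`, `t_max = 200`) over five seeds, about 15 s per run. Unit and
property tests use lattices from 9×9 (reference-equivalence, 2000
replicates) through 61×61 (`smoke` preset) and payoff-corner sweeps on
the 201×201 `calibration` preset with 10 trials per corner. These sizes
were chosen so the full suite exercises every rule at meaningful colony
sizes while remaining comfortably runnable on one CPU.
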