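---
title: "Two-clone germinal center dynamics: model, numerics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-clone germinal center dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gctwoclone)
```

## The biological question

Germinal centers are transient structures in which B-cells proliferate,
hypermutate and are selected by T follicular helper (Tfh) cells. When a
germinal center is seeded by clones of different Tfh reactivity — here a
*broadly reactive* clone drawing weak help from two Tfh families and a
*strain-specific* clone drawing strong help from one — the outcome can be a
monoclonal center producing only one plasma type, or a biclonal one
producing both. Which regime obtains matters for the induction of broadly
neutralizing antibodies, and this package maps the regimes as functions of
the relative selection strength, the seeding composition, the number of
mutational stages required before plasma output, and the forward-mutation
probability.

## Model structure and assumptions

The state comprises, per Tfh family, an available pool $G_j$ and an
unavailable pool $H_j$ (cells/ml), and per B-cell clone a ladder of
mutational stages $B_{j,0},\dots,B_{j,n}$ plus a plasma pool $P_j$ (cells).
Key structural assumptions:

* **No Tfh recruitment or expansion.** Families are seeded once;
  availability is exchanged at rates $\eta$ (loss) and $f$ (regain) per
  competing B-cell, and both pools decay at $d_G$. Consequently
  $G_j + H_j = G_j(0)\,e^{-d_G t}$ exactly — a conservation law the
  integrator is checked against on every run.
* **No explicit antigen.** Antigen effects are folded into the selection
  rates $\sigma$ (strain-specific, per Tfh cell) and $\sigma_c$ (broadly
  reactive). Clone 1 is selected at total rate $\sigma_c (G_1+G_2)$, clone 2
  at $\sigma G_2$; family 2 is engaged by both clones, family 1 only by
  clone 1.
* **Stage ladder with multiplicative bursts.** A selection event moves a
  cell forward with probability $p$ (contributing $\alpha_i$ offspring to
  the receiving stage), backward with probability $1-p-q-d$ (again with the
  receiving stage's $\alpha$), keeps it with $q$, or kills it with $d$.
  The terminal stage has no forward exit; its backward mutations recycle
  into the stage itself as well as feeding stage $n-1$ — both terms are
  present in the equations and are implemented as such.
* **Plasma output above a maturity threshold.** Stages
  $k \ge n_c = \lceil 2n/3 \rceil$ lose cells to differentiation at rate
  $\kappa$ while the plasma pool gains $\alpha_k \kappa B_{j,k}$. The gain
  carries the proliferative factor $\alpha_k$ that the loss term does not;
  this asymmetry is deliberate (it reproduces the published plasma
  magnitudes, e.g. deviations of order $10^4$ cells in the forward-mutation
  sweep) and is kept exactly as the model defines it.

## Parameters

| Parameter | Meaning | Units | Default |
|---|---|---|---|
| `n` | mutational stages | — | 8 (few-stage) / 50 (many-stage) |
| `n_c` | plasma threshold stage | — | `ceiling(2n/3)` |
| `sigma` | strain-specific selection | ml cell⁻¹ day⁻¹ | 1.7e-4 |
| `sigma_c` | broadly reactive selection | ml cell⁻¹ day⁻¹ | `0.5 * sigma` |
| `p`, `q`, `d_del` | forward / neutral / deleterious | — | 0.18 / 0.5 / 0.3 |
| `eta`, `f` | Tfh availability loss / regain | cell⁻¹ day⁻¹ | 1e-5 / 1e-5 |
| `d_G`, `d_B` | Tfh / B-cell death | day⁻¹ | 0.01 / 0.8 |
| `kappa` | plasma production | day⁻¹ | 1.2 |
| `alpha_base` | base offspring number | day⁻¹ | 8 |
| seeding | founders / available Tfh | cells, cells/ml | 50 + 50 / 5000 + 5000 |

Two documented conventions deserve comment, since the defining formulas are
ambiguous at the margins:

* **Proliferation indexing.** The stated anchors "$\alpha_0 = \alpha_1 = 8$"
  and "$\alpha_n = 16$" cannot both hold for the one-line formula
  $\alpha_{i+1} = 8(1+i/n)$ at finite $n$. We adopt $\alpha_0 = 8$,
  $\alpha_i = 8(1+(i-1)/n)$ for $i \ge 1$, which satisfies the first anchor
  exactly and approaches the second as $n$ grows ($\alpha_{50} = 15.84$).
  The schedule is exposed through `proliferation_rate()` and can be
  effectively re-anchored via `alpha_base`.
* **Threshold rounding.** $2n/3$ is non-integral for $n \in \{8, 50, 71\}$.
  We use `ceiling`, which makes the last pre-plasma stage at $n = 50$ stage
  33 — the gateway population tracked by `prepl_stage_trace()`. The choice
  is exposed as the `n_c` override; for $n = 8$ the critical selection
  ratio moves by less than 0.005 across $n_c \in \{5, 6, 7\}$, so the
  regime map is insensitive to it.

## Numerics

* **Integration.** `gc_simulate()` uses `deSolve`'s adaptive `lsoda` with
  `rtol = 1e-8`, `atol = 1e-10`. These tight tolerances make the bisection
  boundaries insensitive to solver error at the $10^{-3}$ level. The system
  is non-stiff at baseline but `lsoda` switches automatically if stiffness
  develops during the collapse.
* **Cross-validation.** `rk4_reference()` is a self-contained classical
  fixed-step RK4 loop over the same right-hand side. The test suite checks
  componentwise agreement within $10^{-5}$ relative (with a one-cell
  absolute floor, so collapsed compartments are compared absolutely) on
  $n = 2$ and $n = 8$, and verifies the fourth-order error scaling of the
  reference itself.
* **Termination.** The model never extinguishes a clone in finite time, so
  "germinal center termination" needs an operational definition: the first
  time after the one-day seeding transient at which total live B-cells drop
  below one cell (configurable `termination_floor`). Integration stops on
  that root; `detect_termination()` applies the same rule to any stored
  trajectory by linear interpolation. At baseline ($n = 8$) this gives
  24.0 days, with floors of 10 / 1 / 0.1 cells giving 18.3 / 24.0 / 29.4
  days — the collapse tail runs roughly five days per decade. Plasma pools
  plateau before the floor is reached, so outcome classification is
  insensitive to the exact floor.
* **Negativity.** Tiny negative values (scale-aware integrator noise) are
  tolerated in trajectories and clipped in summaries; materially negative
  states abort the run.
* **Safety horizon.** 250 days; every regime studied terminates well within
  it.

## Experiments and boundary finding

Sweeps (`sweep_sigma_ratio()`, `sweep_seeding()`,
`sweep_forward_mutation()`) run one integration per grid point and are fully
deterministic. Regime boundaries are located by bisection on boolean
indicators (`find_ratio_threshold()`, `find_seeding_threshold()`): clone
success (final plasma > 100 cells), dominance ($P_1 > P_2$), or biclonality.
Bisection tolerances default to 0.005 (selection ratio) and 0.002 (seeding
fraction), below the two-decimal precision at which the thresholds are
reported. Dominance is defined as a strictly greater final plasma count;
exact ties occur only in the symmetric limit.

Default grids: selection-ratio sweeps cover 0.02–1.00 in steps of 0.02; the
forward-mutation sweep covers $p \in [0.10, 0.20]$ in steps of 0.005, a
range bracketing both reported deviation maxima ($p = 0.12$ at $n = 8$,
$p = 0.20$ at $n = 71$) while keeping the backward probability
$1 - p - q - d \ge 0$. Both grids are configurable.

## What the simulations do and do not show

All inputs are parameter configurations; there is no data fitting here, and
the small-$n$ fixture configurations (`n2_toy`, `n3_toy`) exist for fast
verification, not biology. The model is deterministic and mean-field: it
cannot reproduce the run-to-run variability of real germinal centers, founder
effects at very small cell numbers (a fraction of a cell still contributes
plasma), stochastic extinction, or antigen co-evolution. Quantitative
outputs inherit the uncertainty of the literature-derived rates; the regime
*structure* (monoclonal bands flanking a biclonal band, its widening with
fewer mutational stages, the seeding-bias flips) is the robust product.

Known quantitative caveat: with the equations implemented exactly as
defined, the upper edge of the $n = 50$ biclonal band falls at
$\sigma_c/\sigma \approx 0.71$ and the biclonal-to-monoclonal seeding
boundary at strong broad selection at $\approx 0.27$ — both somewhat above
the published readings (0.62 and 0.24). The same implementation reproduces
the remaining boundaries and the plasma magnitudes closely, and the
alternative plasma formulation that would lower these two numbers (dropping
$\alpha_k$ from the plasma gain) breaks the others badly, so the as-printed
equations are retained. The corresponding checks in the test suite assert
the published values and are expected to fail until the discrepancy is
resolved.

## A short tour

```{r example, eval = FALSE}
params <- gc_parameters(n = 8)
traj <- gc_simulate(params)
summarize_run(traj)

# regime boundary: onset of broadly reactive plasma production
find_ratio_threshold(params, clone = 1, bracket = c(0.05, 0.5))

# seeding bias needed for broad dominance at weak broad selection
p24 <- gc_parameters(n = 8, sigma_c = 0.24 * 1.7e-4)
find_seeding_threshold(p24, criterion = "dominance")

# forward-mutation sensitivity
sweep_forward_mutation(params)[, c("p", "abs_diff")]
```
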