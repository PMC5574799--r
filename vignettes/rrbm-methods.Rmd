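---
title: "Model and methods behind rrbm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind rrbm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrbm)
```

## The model

`rrbm` models the stored resource `y(t)` of a single perennial plant that
can reproduce both sexually and asexually. Each year the plant adds a fixed
surplus `Ps` (photosynthate left after growth and maintenance) to its
store; the seasonal pool `P = y(t) + Ps` is then compared with two
thresholds, a lower one `L1` for asexual reproduction and a higher one `L2`
for sexual reproduction:

* **RA** (`P < L1`): the pool is banked unspent;
* **AR** (`L1 <= P < L2`): asexual reproduction spends `C_v = d (P - L1)`;
* **SAR** (`P >= L2`): the plant flowers and buds simultaneously, spending
  `C_f = p (P - L1)` on flowers, `C_v = q (P - L1)` on asexual offshoots,
  and `C_a = R C_f` on setting the seed of pollinated flowers.

The reserve then updates by exact conservation,
`y(t+1) = y(t) + Ps - (C_f + C_a + C_v)`. All three branches are linear in
`y`, with slopes `1`, `1 - d` and `1 - (p + q + R p)`; everything the
package computes follows from that piecewise linearity.

Assumptions inherited from the resource-budget family: constant annual
surplus (no environmental stochasticity), a single plant (no pollen
coupling or population synchrony), reproduction costs proportional to the
pool in excess of the *asexual* threshold, and no trade-off between growth
and reproduction. The reserve is deliberately **not** floored at zero:
when the total flowering-year allocation `p + q + R p` exceeds 1 the plant
overdraws its store, and that overdraft is the engine of masting cycles.
The constructor signals a warning (class `rrbm_overdraft`) in that case
rather than rejecting it.

## Parameters

| symbol | meaning | units | constraint | default/notes |
|---|---|---|---|---|
| `L1` | asexual reproduction threshold | resource | `L1 < L2` | scenario-specific |
| `L2` | sexual reproduction threshold | resource | — | scenario-specific |
| `Ps` | annual surplus | resource/yr | `> 0` | 3 in the bundled scenarios |
| `p` | flowering coefficient | — | `(0, 1)` | trade-off with `q` |
| `q` | asexual coefficient (SAR year) | — | `(0, 1)` | |
| `d` | asexual depletion (AR year) | — | `(0, 1)` | kept independent of `q` |
| `R` | seed-set : flowering cost ratio | — | `> 0` | 1–9 in the sweeps |

`d` and `q` both scale asexual spending but on different branches; the
model treats them as independent traits and the package follows suit. A
`reduction = TRUE` mode relaxes the invariants to `L1 == L2`, `p == 1`,
`q == 0`, which empties the AR band and recovers the classic
single-threshold budget model `y + Ps - (1 + R)(y + Ps - L)`; the test
suite verifies that reduction against an independently coded one-line
oracle (to machine precision — the two algebraically identical expressions
differ by rounding order, so bitwise equality is not a meaningful target).

## Threshold ties

The tie-breaks at the thresholds are measure-zero for generic parameters
but not for the bundled scenarios, which start at `y0 = 0` with
`Ps = 3 = L2` in the `fig1c`/`fig1d` geometry, so the pool hits `L2`
*exactly* in year one. The package resolves ties as `P == L1 -> AR` (cost
zero, seamless with RA) and `P == L2 -> SAR` (a pool reaching the sexual
threshold flowers). The second choice is load-bearing: under the opposite
convention the `fig1c` orbit's first step is an AR year that deflects it
into the basin of a coexisting stable AR/SAR 2-cycle, and it never reaches
the flowering equilibrium `y1* = 0.875` — contradicting the constant
annual reproduction that scenario is defined to exhibit. Flowering at the
threshold reproduces it.

## Equilibria, stability, regimes

Setting `y(t+1) = y(t)` on each reproductive branch gives the two
closed-form equilibria reported by `asexual_fixed_point()` and
`sexual_fixed_point()`; each is valid only while it actually lies on its
branch, which is what the existence conditions `Ps < (L2-L1) d` and
`Ps > (p+q+Rp)(L2-L1)` express. Because each branch is linear, the
analytic Lyapunov exponent at an equilibrium is just the log absolute
slope of its branch, and `lyapunov_numeric()` averages the same quantity
along a simulated orbit — the two agree exactly whenever the post-burn-in
orbit stays on one branch, which the tests exploit as an oracle.

`classify_regime()` reports four scenes: (1) asexual equilibrium, stable
whenever it exists since `|1-d| < 1`; (2) no equilibrium — masting cycles;
(3) stable flowering equilibrium (`Rp < 2-p-q`); (4) unstable flowering
equilibrium. Numerical conventions:

* all comparisons are strict; a governing quantity within `1e-12` of
  equality yields scene 0 (boundary) and `exists = FALSE`, so measure-zero
  cases are visible rather than silently assigned;
* `|λ| <= 1e-12` is reported as `"marginal"`, a state of its own;
* the scene conditions are *not* mutually exclusive: when
  `d > p + q + R p` both existence conditions can hold at once and both
  equilibria genuinely coexist on their branches. The classifier applies
  the rows in order, so such sets report scene 1 — consistent with the
  dynamics from an empty store, which cannot climb through the AR band
  past the asexual equilibrium.

A caution the test suite makes explicit: scene 3 guarantees only *local*
stability of `y1*`. The piecewise-linear map is multistable — a stable
AR/SAR cycle can coexist with the stable flowering equilibrium, and for
roughly one in ten random threshold geometries the orbit from `y0 = 0`
lands on the cycle instead. Scene 1, by contrast, is globally attracting
from an empty store (the pool can never jump the AR band when
`Ps < d (L2-L1)`), and the suite asserts exactly these two different
strengths.

## Period classification

`period_code()` simulates `burn_in + window` years and encodes the
post-burn-in flowering pattern on the phase-diagram colour bar: `-1` no
flowering year in the window; `0` flowering every year on a constant
orbit; `1` flowering every year on a non-constant orbit (the colour bar
distinguishes "sexually every year" from "every 1 year"; the package
makes that well defined by reserving `0` for the fixed point); `2`–`18` a
constant inter-flowering interval; `19` longer than 18 years or irregular.
A single flowering event in the window also codes `19` (period
unresolved). Defaults: `y0 = 0`, `burn_in = 1000`, `window = 2000`,
`tol = 1e-9`.

Constancy for the 0-vs-1 call is judged on the **final 100 window years**,
not the whole window: near `|1 - (p+q+Rp)| = 1` the geometric transient
decays so slowly that after 1000 burn-in years an orbit can still carry a
few-nanounit amplitude at the window's start while being constant to
machine precision at its end. The code describes the attractor, so the
terminal segment is the right witness; interval regularity, in contrast,
locks in quickly and is judged on the whole window.

`rrbm_sweep()` tiles the open unit square of `(p, q)` (an `N`-point axis
samples midpoints `i/(N+1)`, so the excluded endpoints are never touched)
at each requested `R`. Cells are independent; a cell that trips the
`1e12` divergence guard is recorded as the sentinel `-9` instead of
aborting the sweep. The `simplex` option restricts to `p + q <= 1` for
questions about allocation fractions that must share one pool.

## Numerical choices

* Double precision throughout; the core iteration is compiled, and the
  one-year R step, the trajectory recorder and the orbit sampler share one
  arithmetic expression, so conservation
  `y_next - y_start - Ps + (C_f+C_a+C_v) = 0` holds to `1e-12` by
  construction and trajectories are bit-reproducible run to run.
* Trajectory CSVs serialize floats with 17 significant digits, enough for
  IEEE doubles to round-trip bit-exactly.
* Reserves may legitimately go negative; only `|y| > 1e12` aborts (error
  class `rrbm_divergence_error`, carrying the year), since a reserve of
  that magnitude can only mean runaway parameters.
* The model has no stochastic component; `simulate()` accepts a `seed`
  argument purely for generic-signature compatibility.

## What the test draws emulate — and what they do not

The property suites draw parameters uniformly: thresholds `L1` in
(0.5, 4) with a band `L2 - L1` in (0.2, 4), surplus `Ps` in (0.3, 5) —
spanning the bundled worked-example geometries — the allocation
coefficients across their full open `(0, 1)` ranges, and `R` in
(0.2, 10), covering the sweep range. These draws probe the map's logic
(conservation, fixed-point algebra, regime/dynamics coherence), not the
biology of any particular species: real masting data feature
environmental noise on the surplus, threshold variation between years, and
population-level synchrony, none of which this single-plant deterministic
map contains. Passing tests certify the dynamical theory of the model, not
its fit to field data.

Problem sizes: module tests simulate 20–300 years per draw with up to
1000 draws per property; period classification uses the 1000/2000-year
burn-in/window defaults; phase-diagram checks run 51x51 grids at five
values of `R` (about 13,000 cells), which completes in a few seconds
thanks to the compiled core.

## Known limitations

* Single plant, deterministic: no pollinator coupling, no synchrony, no
  stochastic surplus or thresholds.
* The threshold ordering is fixed at `L1 < L2`; species whose asexual
  threshold sits above the sexual one (or coincide outside the reduction
  limit) are out of scope.
* Period codes are attractor labels from one initial store (`y0 = 0` by
  default). Under multistability a different `y0` can land on a different
  attractor and hence a different code; the phase diagrams are therefore
  conditional on the empty-store start, which is also the natural
  post-establishment state.
* The maximum recognized period is 18 years; longer cycles are lumped
  into code 19 by design.
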