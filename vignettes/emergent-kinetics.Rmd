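---
title: "Emergent nutrient transport and growth kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emergent nutrient transport and growth kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutrikin)
library(ggplot2)
```

## The problem

Nutrient-limited phytoplankton growth is almost always summarized by a Monod
curve: a maximum growth rate $G_{max}$ and a half-saturation constant $K_G$,
both treated as species constants. Physiologically, however, $K_G$ is not a
constant of anything. Transport of dissolved nutrients (ammonium, nitrate,
phosphate) is performed by transporter proteins in the plasma membrane, each
with its own Michaelis--Menten half-saturation $K_T$ defined at the membrane
surface; the concentration at the membrane ($S_0$) differs from the bulk-water
concentration an observer measures ($S_\infty$) by a diffusive boundary-layer
gradient; the number of active transporters is regulated up and down with the
cell's nutritional status; and the demand side depends on cell size, carbon
density (vacuolation) and elemental stoichiometry. `nutrikin` chains these
mechanisms and lets $K_G$ — the bulk concentration supporting $G = G_{max}/2$
— *emerge* from the chain.

## The model

**Quota control of growth.** The cellular N:C mass ratio $NC$ runs between
$NC_{min}$ (growth stops) and $NC_{max}$ (growth maximal). Its normalized form

$$NCu = \frac{(1+K_Q)\,(NC-NC_{min})}{(NC-NC_{min}) + K_Q\,(NC_{max}-NC_{min})} \in [0,1]$$

controls growth as $G = G_{max}\,NCu$. With the default $K_Q = 10$ the
N:C-to-growth map is near-linear (within 5% of the chord; this is asserted in
the test suite). The inverse map is closed-form, so any target growth rate
corresponds to exactly one quota.

**Steady-state demand.** A cell of carbon content $C_{cell}$ (pgC) growing at
$G$ with quota $NC$ must import $T = G \cdot NC \cdot C_{cell}$ pgN d$^{-1}$.

**Transport capacity and its regulation.** Transport capacity is bounded per
unit membrane area: the transporter rate density (TRD) cannot exceed
`TRD_max` (default 0.4 pgN µm$^{-2}$ d$^{-1}$). Sustaining $G_{max}$ requires
$TRD_{Gmax} = G_{max} NC_{max} C_{cell} / SA$; if that exceeds `TRD_max` the
configuration is infeasible and `organism()` refuses to build it. The
headroom $T_{add} = (TRD_{max}-TRD_{Gmax})/TRD_{Gmax}$ feeds the hypothetical
up-regulation curve

$$T_{max} = G_{max} NC_{max}\left(1 + T_{add}\,
  \frac{(1+KT_{con})(1-NCu)}{(1-NCu)+KT_{con}}\right),$$

which sits at the replete floor $G_{max} NC_{max}$ when $NCu = 1$ and rises
towards $(1+T_{add})$-fold under extreme stress; `KT_con` (default 0.1) sets
the steepness, and the normalized bracket runs 0--1 for any `KT_con`. Three
capacity modes are available: this curve (`"eq5"`, the default), a flat
capacity pinned at the floor (`"flat"`, the implicit assumption of most
ecosystem models), and interpolation of tabulated empirical capacity curves
(`"empirical"`).

**Membrane kinetics and the boundary layer.** Demand is met through
Michaelis--Menten transport, inverted for the membrane concentration
$S_0 = T K_T/(T_{max,cell} - T)$, and the demand must also be delivered by
diffusion across the boundary layer:

$$S_\infty = \frac{T}{4\pi D r\,(1 + 0.5\,r c/D)} + S_0,$$

where the $(1 + 0.5\,rc/D)$ factor is the Péclet-like thinning of the
boundary layer by motion at speed $c$ — swimming for flagellates
($c = 38.542\,ESD^{0.5424}$ µm s$^{-1}$) or Stokes sedimentation for diatoms
($c_{sed} = 2 g r^2 (\rho_{org}-\rho_w)/(9\eta)$).

**The forward chain.** `solve_state_at_growth()` therefore maps
$G \to NCu \to NC \to T \to T_{max} \to S_0 \to S_\infty$ deterministically,
with no iteration, and

$$K_G = S_\infty(G_{max}/2) = \underbrace{S_0}_{\text{transporter}} +
        \underbrace{S_\infty - S_0}_{\text{diffusion}}.$$

`half_saturation_growth()` evaluates this directly at $NCu = 0.5$ — the
operating point is exact, so no root-finding is involved — and reports both
components.

```{r worked}
org <- organism(10, carbon = "C150")
half_saturation_growth(org)
```

## Parameters

| Parameter | Unit | Default | Meaning |
|---|---|---|---|
| `ESD` | µm | — | equivalent spherical diameter |
| `NC_max`, `NC_min` | gN gC$^{-1}$ | 0.18, 0.05 | quota bounds for N-limited growth |
| `KQ` | — | 10 | quota curve shape (10 = near-linear) |
| `G_max` | d$^{-1}$ | 0.693 | maximum growth rate (one doubling/day) |
| `K_T` | µM | 1 | transporter half-saturation at the membrane |
| `TRD_max` | pgN µm$^{-2}$ d$^{-1}$ | 0.4 | membrane ceiling on transporter rate density |
| `KT_con` | — | 0.1 | steepness of capacity up-regulation |
| `D` | m$^2$ s$^{-1}$ | 1.5e-9 | nutrient diffusivity |
| `rho_org`, `rho_w` | kg L$^{-1}$ | 1.0634, 1.033 | organism and seawater density (Stokes law) |
| `eta` | Pa s | 1.0846e-3 | seawater dynamic viscosity |

Internally lengths are µm, time is days, masses are pg, and concentrations
are µM at every API boundary (1 µM N = 14 µg L$^{-1}$ = 1.4×10$^{-8}$
pg µm$^{-3}$; see `pg_per_um3()`). Speeds are accepted in µm s$^{-1}$ and
converted to µm d$^{-1}$ internally, keeping the diffusion equation on a
single time base.

## Carbon models

Three presets map volume to carbon. `C150` fixes density at 150 gC L$^{-1}$.
`Cprot` and `Cdiat` use the standard piecewise carbon-to-volume power-law
regressions for protist plankton, which differ between size classes: below
3000 µm$^3$, $C = 0.261\,V^{0.86}$ (protists) and $C = 0.288\,V^{0.811}$
(diatoms); above it, $C = 10^{-0.665}\,V^{0.939}$ and
$C = 10^{-0.933}\,V^{0.881}$. The size-class split matters: a single
small-cell power law extrapolated to 80 µm cells understates carbon density
enough to flatten the affinity-scaling exponents well beyond their
uncertainty, while the piecewise relations reproduce both the small-cell
worked budgets and the scaling regressions. A generic single-segment model
remains available via `carbon_model("allometric", a =, b =)`. For Stokes
sedimentation the organism density is held at 1.0634 kg L$^{-1}$ at all
sizes, even though vacuolate cells are in reality less dense; no
variable-density sedimentation model is offered (see Limitations).

The diffusivity default (1.5×10$^{-9}$ m$^2$ s$^{-1}$, typical of small
inorganic N ions near 20 °C) is exposed in `marine_environment()`; the
scaling *exponents* of affinity against size are insensitive to it, but the
prefactors are not, so only exponents should be compared across studies.

## What the package computes

```{r scan, fig.width = 6, fig.height = 3.5}
scan <- esd_scan(carbon = "Cdiat", motion = "sink")
autoplot(scan)
power_fit(scan)
```

`esd_scan()` uses 25 log-spaced diameters on [2, 80] µm by default — enough
points for a stable log--log regression over the size range typical of
nano- and microplankton; `power_fit()` estimates the scaling
$G_{max}/K_G = a\,ESD^{b}$ by OLS on log10 values. Affinity falls with size
with $b$ between about −1.6 (fixed density, non-motile) and −0.8
(sedimenting diatom): motion and vacuolation mitigate, but never cancel,
the size penalty. `reproduce_scaling_fits()` runs all six standard
configurations; `reproduce_cell_budgets()` recomputes the worked per-cell
budgets for three reference species and reports relative deviations from
the published reference values (all within their rounding).

Because the whole chain scales linearly in $G_{max}$ at fixed $NCu$ (demand
∝ $G$, capacity ∝ $G_{max}$), the ratio $G_{max}/K_G$ is nearly invariant in
$G_{max}$ — "nearly" because the quota inverse introduces a weak
nonlinearity; the suite asserts invariance within 10% over
$G_{max} \in [0.2, 1.4]$ d$^{-1}$. Slower-growing strains therefore come
with proportionally lower $K_G$.

**The hyperbola is a biased summary.** An emergent $(S_\infty, G)$ curve
from `kinetic_curve()` is not a rectangular hyperbola: capacity
up-regulation and diffusion make it steeper near the origin and flatter at
the plateau. `fit_rht2()` (Levenberg--Marquardt, initialized from a
double-reciprocal estimate; either both parameters free or the maximum
fixed at $G_{max}$) fits such curves with $R^2 > 0.98$ — and still
systematically overestimates growth at $S_\infty = K_G$. Good fit
statistics do not validate the Monod form.

```{r rht2, fig.width = 5, fig.height = 3.2}
kc <- kinetic_curve(organism(20, carbon = "Cprot"), n = 150)
autoplot(fit_rht2(kc))
```

## Synthetic data

Two generators provide test inputs with the structure the analysis assumes,
so every stage is testable without external data.

`gen_uptake_experiment()` emulates a short-incubation uptake assay: a true
hyperbola on a log-spaced substrate grid under multiplicative lognormal
noise of a given CV (mean-one; rate error scales with magnitude, which is
why the noise is multiplicative rather than additive). `gen_tmax_table()`
emulates empirically derived capacity-versus-N:C curves: a rise from a
replete floor (default $G_{max} NC_{max}$, the capacity just sufficient for
maximal growth) to a peak at moderate stress, collapse at extreme stress,
and optional nitrate-style repression below the floor near the replete end.
The curve is two smooth half-waves joined with zero slope at the peak, so
it is continuously differentiable and strictly unimodal. Both generators
thread an explicit seed through `withr::with_seed()` and never touch the
global RNG state.

What the generators do *not* emulate: incubation-time satiation dynamics,
biphasic or multiple transporter systems, correlated measurement error, and
the specific published datasets behind real capacity curves. Passing tests
demonstrate internal consistency of the estimation machinery under the
stated noise model, not fidelity to any particular experiment. Under the
default design (n = 20, CV = 10%), the median fitted $K$ across 500 seeds
is within 5% of truth, while the median *absolute* error of a single
experiment is around 9% — single-assay half-saturation estimates are simply
that uncertain.

## Numerical choices and degenerate inputs

* $K_G$ is evaluated directly at $NCu = 0.5$; no solver tolerances exist
  anywhere in the forward chain.
* In `"eq5"` mode the replete capacity floor equals the replete demand
  exactly, so $G = G_{max}$ itself is a saturation point; sweeps default to
  stopping at $0.995\,G_{max}$, and saturated grid points are dropped with
  a warning rather than silently interpolated.
* Demands at or beyond capacity raise a typed saturation error
  (`nutrikin_saturated`); trait sets whose $TRD_{Gmax}$ exceeds the membrane
  ceiling raise a typed infeasibility error (`nutrikin_infeasible`) at
  construction, and `esd_scan()` records such sizes as infeasible rows
  rather than dropping them.
* Empirical capacity tables are interpolated with monotone
  (Fritsch--Carlson) piecewise cubics: no overshoot between knots, hence no
  spurious negative or super-peak capacity; out-of-range queries clamp to
  the end knots with a warning.
* Hyperbola fits fix non-finite or non-positive double-reciprocal starting
  values back to robust fallbacks (max rate, median substrate) before the
  nonlinear step; non-convergence raises a typed fit error rather than
  returning a half-fitted object.

## Limitations

Cells are spheres; chains, colonies and non-spherical forms are out of
scope, as are mixotrophy, multiple transporter systems per nutrient,
ammonium--nitrate interactions, and light or temperature co-limitation.
Organism density for sedimentation does not track vacuolation. The model
describes steady-state balanced growth: transient dynamics of satiation
feedback are outside its scope. $K_G$ values are predictions of a
mechanistic idealization — their absolute scale inherits the uncertainty of
$K_T$, `TRD_max` and $D$; ratios, decompositions and scaling exponents are
the robust outputs.
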