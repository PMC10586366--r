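---
title: "Methods: landscape-scale aquatic pesticide exposure and effect simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: landscape-scale aquatic pesticide exposure and effect simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

aquarisk simulates the chain *application → spray drift → water–sediment
fate → individual survival → landscape risk end points* for a pesticide
used on orchards along a river network. This vignette is the package's
account of the science: the models and their assumptions, the parameters
that matter, the numerical choices, and what the synthetic test bed does
and does not demonstrate.

## Scenario model

A landscape scenario consists of a reach network (a directed tree with one
outlet; each reach carries length, trapezoidal cross-section parameters,
Manning's *n*, longitudinal slope, drainage area, Strahler order and an
assumed drift-interception surface width), orchard polygons, a wind rose,
substance properties, an application setup, an hourly outlet discharge
series and a daily temperature series. All coordinates are planar metric;
the package performs no reprojection, because drift distances and buffer
widths are metric quantities.

Strahler orders follow the classical rule (headwaters are order 1; a
junction of two equal maximum orders increments the order, otherwise the
maximum propagates) and are used to assign channel geometry from a
per-order lookup — the standard parameterisation when surveyed
cross-sections are unavailable.

Two scenario conventions deserve a note:

* **Calendar.** Simulation years are fixed 365-day years (8760 h). This
  keeps annual application windows and the whole-year survival windows
  exact across arbitrary simulation lengths; timestamps written to CSV use
  a leap-free month table. For a risk simulator driven by synthetic or
  climatological forcing this costs nothing and removes a class of
  off-by-one-day artefacts.
* **Temperature.** The fate module consumes the trailing three-day mean of
  daily temperature. The first three days, which lack a full window, are
  padded with the first available mean; any artefact is absorbed by the
  warm-up period.

## Synthetic catchment generator

The generator exists so the full chain runs, and is *tested*, without any
external geodata. It emulates the composition of a small lowland orchard
catchment:

* a Galton–Watson-style tree grown upstream from the outlet with at most
  two tributaries per junction; the probability that a new reach starts a
  tributary rather than extending a headwater chain (`branch_prob`,
  default 0.42) is set so that order-1 reaches make up roughly 55 % of the
  network at n ≈ 100–200, the headwater share typical of dense lowland
  drainage networks;
* reach lengths drawn around a 100 m median and clamped to 5–110 m,
  reflecting how practical network digitisation splits watercourses;
* lognormal local drainage areas (median ~8.8 ha per reach) accumulated
  downstream, and an hourly outlet discharge equal to drainage area times
  a specific yield of 3.6e-5 m³/h/m² (~10 L/s/km², a humid temperate
  value), modulated by a winter-peaking seasonal sinusoid (relative
  amplitude 0.6) and daily lognormal noise (sdlog 0.25);
* channel geometry by Strahler order spanning bottom widths 0.4–6 m and
  slopes 0.004–0.001, which yields depths of centimetres to decimetres and
  advective residence times of minutes — the regime in which drift pulses
  are "peaky and short";
* rectangular orchards (80 m × 120 m) flanking a configurable fraction of
  reaches (default 0.35) at 3–40 m from the bank, and a uniform
  eight-sector wind rose by default.

What the generator does **not** emulate: real catchment shapes and stream
sinuosity, spatially correlated orchard clusters, gauged discharge with
storm events, or wind roses with persistent directions. Tests passing on
synthetic catchments therefore demonstrate the correctness and the
qualitative spatial patterns of the chain (dilution with order, upstream
variability, transfer-only exposure downstream), not calibrated agreement
with any real catchment.

## Hydrology

Per-reach discharge is the outlet series scaled by the drainage-area ratio
(catchment-area-yield). Water depth solves Manning's equation for a
trapezoidal section,

$$Q = \frac{1}{n} A(d)\, R(d)^{2/3} S^{1/2}, \qquad
A = d(b + s d), \quad R = A / (b + 2 d \sqrt{1+s^2}),$$

by bisection on [floor, 10 m] to 1e-8 m. Discharge is strictly monotone in
depth, so the bracket is unconditionally valid; Newton iteration was
rejected because the rectangular corner (s = 0) and the floor boundary
make its convergence less robust for no practical speed gain. Zero (or
very small) discharge returns a configurable minimum depth floor, 0.01 m
by default — the shallowest water level worth simulating, and the
guarantee that reach volume never vanishes. Velocity is Q/A and volume is
A·L; residence time is 60·V/Q minutes with an infinite sentinel at Q = 0.

Hydrology is externalized with respect to fate: `compute_hydrology()`
materialises reach × hour series (and round-trips through CSV), while the
routing kernel recomputes the identical quantities internally so that
multi-decade runs never hold full hydrology matrices in memory.

## Spray drift

One application event per orchard per year, uniform over the configured
window (April 20–30 by default), at noon. One wind direction per event is
drawn from the rose (sector by probability, uniform within sector). A
reach is downwind when the bearing from the orchard centroid to its
nearest centreline point lies within ±45° (inclusive) of the downwind
direction; 45° is half the width of the conventional eight-sector rose,
and the inclusive boundary makes the test deterministic on exact sector
edges.

Areic deposition follows a power-law distance curve, `pct(z) = A·z^B` per
cent of the applied areic rate, averaged exactly (analytic antiderivative)
over the water-surface band `[z, z + w]`, where `w` is the reach's drift
surface width. The defaults A = 60, B = −1.7, valid over 1–250 m, are an
illustrative orchard-like parameterisation: curve calibration is expressly
out of scope and the coefficients are configuration. Distance is the
minimum orchard-edge-to-centreline distance minus half the surface width,
floored at zero; one representative distance per orchard–reach pair is
used because reaches are ~100 m and deposition is defined as the mean rate
over the reach surface. The no-spray buffer acts as a minimum effective
drift distance (`z = max(distance, buffer)`): it mitigates the
application, rather than removing orchard area from the scenario.
Deposition mass is therefore exactly linear in application rate and in
(1 − drift reduction), and non-increasing in distance — all three are
asserted as properties in the tests.

## Water–sediment fate

Each reach is a well-mixed bucket with two compartments: the water column
(dissolved plus sorbed to suspended solids, which advects) and a single
well-mixed sediment layer (pore water plus sorbed). With `fd = 1/(1 +
Koc·foc_ss·SS)` the dissolved fraction, the within-hour dynamics are
linear with constant coefficients:

$$\frac{dW}{dt} = -(k_{adv} + k_{deg,w} + f_d k_{vol}) W
  - E\left(\frac{f_d W}{V_w} - \frac{S}{V_{sed}^{eff}}\right), \qquad
\frac{dS}{dt} = +E\left(\frac{f_d W}{V_w} - \frac{S}{V_{sed}^{eff}}\right)
  - k_{deg,s} S,$$

with `k_adv = Q/V`, first-order degradation `ln 2 / DT50` per compartment
(Arrhenius-corrected with a default molar activation energy of 65.4
kJ/mol, the surface-water modelling convention, from a 20 °C reference),
exchange conductance `E = v_ex · A_bed` and an effective sediment capacity
`V_sed^eff` combining pore water and organic-carbon sorption
(porosity + ρ_b·Koc·foc_sed).

**Numerics.** Because the hourly system is linear with constant
coefficients, it is advanced with the exact 2×2 matrix exponential, and
hourly averaged concentrations are the exact time integrals of the
solution (stable `expm1`-based forms cover the nearly-degenerate
eigenvalue cases, including the mass-conserving pure-exchange limit).
This replaces the more obvious operator-split sub-stepping at a fraction
of the residence time: with residence times of minutes against a 1 h
output step, splitting would need dozens of sub-steps per hour for
accuracy the closed form delivers exactly, at lower cost and with
machine-precision mass balance. The consequences are directly testable —
the single-reach pulse reproduces the CSTR solution `(M0/V)e^{−Qt/V}`
exactly, the cumulative mass ledger closes to ~1e-14 relative, and the
chain is exactly linear in inputs (the property that justifies the LP50
multiplication-factor approach).

Reaches are processed in topological order within each hour; the advected
outflow of a reach becomes downstream inflow in the same hour. The
alternative (next-hour transfer) would add a spurious one-hour lag per
reach — noticeable over chains of 100 m reaches with minute-scale
residence times. Drift and upstream inflow are mixed instantaneously over
the reach (bucket assumption; no longitudinal dispersion within a reach).
Warm-up years are simulated but excluded from the returned concentration
field. The sediment is deliberately a single layer rather than a
discretised diffusion profile: a documented simplification that preserves
total sediment capacity and exchange-limited kinetics but not
within-sediment gradients.

## Effects: GUTS-RED and LP50

The reduced GUTS model uses scaled damage as the dose metric,
`dD/dt = k_d (C − D)`, integrated exactly per hour against the
piecewise-constant exposure. Stochastic death (SD) accumulates hazard
`b·max(D − z, 0) + h_b` (trapezoid on the hourly grid); individual
tolerance (IT) draws a fixed threshold per individual from a log-logistic
distribution, so survival depends only on the running damage maximum.
Both variants are always computed. Years are independent: damage does not
carry over, matching an assessment convention of annual cohorts.

LP50 is the factor `f` on the whole annual profile halving end-of-year
survival *relative to the unexposed control*, `S_f/S_0 = 0.5`. The
relative definition was chosen over absolute survival because with
background mortality `h_b > 0` the absolute target can be infeasible even
for extreme factors, making the end point undefined exactly where it
should be conservative; the relative form removes `h_b` from the
criterion. The search is bisection on `log10 f` between 1e-8 and the 1e5
cutoff to 1e-4 relative tolerance; monotonicity of damage in `f`
guarantees the bracket. All-zero profiles return a `NO_EXPOSURE` sentinel
(no LP50 can be calculated), factors beyond the cutoff `ABOVE_CUTOFF`.
Because TK is linear, LP50 scales inversely with profile magnitude — an
invariant the tests check against independent bisections, and the IT
variant additionally admits the closed form `LP50 = m_w / max D`, used as
an oracle.

The three shipped species parameter sets are **illustrative placeholders**
(plausible magnitudes for a fast-acting hydrophobic insecticide on an
isopod, a mayfly and an amphipod); any real assessment must supply
calibrated, substance-specific values through `guts_params()`.

## Risk end points

* **PECmax** — annual maximum of hourly averaged water concentration per
  reach; a 1e-6 µg/L reporting floor flags negligible values without
  truncating the simulation.
* **Pooled percentiles** — over all reach × year values; both a linearly
  interpolated estimator (default) and a count-based one are exposed,
  since with 20 assessment years statements like "90 % of years" sit
  exactly on an order statistic and the two conventions differ.
* **Rank matrices** — columns are reaches, rows years; years sorted within
  reaches and reaches sorted by their extreme value so the highest PECmax
  (or lowest LP50) sits in the bottom-left corner; column ties break by
  reach id. The derived exceedance statistic reports what fraction of
  reaches crosses a bound in at most a given fraction of years.
* **Worst-year category maps** — per reach, the year at a lower percentile
  of its LP50 values (the 5th percentile of 20 years is the worst year),
  binned into `<1`, `1–10`, `10–100`, `100–1e5`, `effect-free`,
  `no-exposure`. Bins are left-closed (`[1, 10)` is "1–10"); the ordering
  places finite values below `ABOVE_CUTOFF` below `NO_EXPOSURE`, i.e.
  sentinels count as no-concern outcomes.

## Orchestration and reproducibility

`run_pipeline()` executes the stages in consecutive order through a
plain-file run store (GeoJSON/CSV/JSON products plus a manifest); no stage
exchanges data with another except through the store, so any stage can be
re-run from stored upstream products. One master seed spawns named
per-component RNG streams (generator, application dates, wind), so
component-level reproducibility survives changes elsewhere; identical
configuration and seed give byte-identical outputs. A thin Rscript CLI
(`inst/exec/aquarisk.R`) wraps scenario generation, runs and reporting.

## Problem sizes and test design

The test suite exercises the chain at sizes chosen to finish in minutes
while still covering multi-year, multi-order networks: unit checks on 1–5
reach fixtures; property tests on 20–60 reach catchments over 1–3 years;
a 200-reach 3-year run for mass-balance closure; and a full 100-reach,
6 + 20 year end-to-end run with both GUTS variants, which doubles as the
seed-reproducibility check. `scripts/acceptance.R` re-runs the 100-reach
configuration and reports the main end points it computes.

## Known limitations

Spray drift is the only entry route; runoff, erosion and drain flow are
not represented, which understates exposure for mobile compounds. The
hydrology contract is area-yield scaling from a single outlet series;
multi-gauge splitting is an extension point. The drift curve and species
parameters are configuration with illustrative defaults. Survival
modelling is individual-level with no recovery, reproduction or movement,
so end points address threshold-type protection goals only; and a single
simulated period means the lowest resolvable temporal percentile is one
year in twenty — ensemble (multi-seed) runs can be concatenated with the
seed-controlled repeat facility but no formal Monte-Carlo stacking is
provided.
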