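---
title: "One-dimensional vFFR: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{One-dimensional vFFR: models, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vffr1d)
```

## The model

`vffr1d` computes a virtual fractional flow reserve — the simulated
distal-to-aortic pressure ratio Pd/Pa — from a centreline radius profile
r(s) and two boundary conditions: aortic pressure Pa (mmHg) and
microvascular resistance MVR (Wood units). The flow model is steady,
incompressible, rigid-walled and one-dimensional: the vessel is a
sequence of 200 discretised radii, pressure is marched from inlet to
outlet, and the only cross-sectional information retained is lumen area.
Pulsatility, vessel compliance, curvature and secondary flow are all
outside the model class.

Within healthy sections the pressure gradient is Poiseuille,
`-dP/ds = 8 μ Q(s) / (π r(s)⁴)`, optionally augmented by a
momentum-correction advection term (below). Axial flow `Q(s)` is
depleted by a side-branch leakage density `q(s) ≥ 0` (m³/s per metre),
whose total is fixed by the Huo–Kassab morphometric scaling law applied
to the healthy-lumen endpoints:
`Q_in/Q_out = (R_in/R_out)^(7/3)`. The five models differ only in how
that budget is distributed:

* **none** — `q ≡ 0`;
* **homogenous** — constant over healthy points;
* **localized** — proportional to `max(0, -d/ds r_h^{7/3})`, the
  negative gradient of the same quantity the scaling law is built on, so
  the local weight and the global budget share one physical basis.
  Radius-recovery regions get zero weight;
* **conductance** — wall conductances `g(s) = q_localized(s)/P_ref(s)`
  with the reference pressure taken from a localized-leak run of the
  *stenosis-free* geometry, then `q = g·P` iterated with the actual
  pressure field. Equal tapers therefore share equal conductance, and
  pressure loss across a stenosis damps leakage distal to it;
* **porosity** — a Darcy–Forchheimer transmural law
  `P = q/k(s) + β q²` (venous reference pressure 0) with per-point
  Darcy conductance `k(s)` proportional to the localized taper weight.
  The proportionality constant is calibrated by fixed-point iteration on
  the stenosis-free geometry so that the unstenosed vessel reproduces
  the Huo–Kassab flow ratio; the Forchheimer coefficient β defaults to 0
  and is exposed in `porosity_config()`.

Stenosed sections — found by the healthy-lumen filtration described next
— carry no leak and use an empirically lumped drop: the Poiseuille
integral over the actual interval radii plus an expansion loss
`kt (ρ/2) (A_h/A_min − 1)² (Q/A_h)²` applied at the interval exit.

## Healthy-lumen estimation

The hypothetical disease-free lumen is estimated by Fourier filtration
of the cross-sectional area signal `a(s) = π r(s)²`. The fit basis is
the lowest `n_harmonics` mirror-even Fourier modes
(`cos(jπs/L)`) plus a linear trend; the trend term represents baseline
taper exactly, so the harmonics only need to carry slow deviations from
it. The fit is iterated as a robust upper envelope:

1. warm start: an asymmetric (90th-centile) fit of the trend alone.
   A fit this coarse cannot follow a lesion, and the one-sided loss
   keeps it on the healthy flanks however wide the lesion is;
2. points falling below the fit by more than
   `max(2σ_up, 0.5% of area)` are excluded, where `σ_up` is a scale
   estimated from the *upper* residuals only (lesions only ever sit
   below the envelope, so the upper side is uncontaminated);
3. the full basis is refitted (again at the 90th centile) on the
   included points, and steps 2–3 repeat until the excluded set and the
   fit stabilise.

A point is stenosed when its observed area falls strictly below
`area_threshold` (default 0.80) of the fitted healthy area. Two
morphological cleanups follow: single-point gaps inside a flagged run
are bridged, and runs shorter than `min_run = 2` points are dropped.
Both rules are this package's choices; the threshold's strictness
(exactly 80% is healthy) follows the definition of the stenosis rule.

Why `n_harmonics = 4`? On a 200-point profile of a vessel a few
centimetres long, the cutoff wavelength of the fourth mirror-even mode
is well above the spatial extent of focal lesions, so a lesion cannot be
absorbed into the fit; with 8 harmonics a 2 mm-wide lesion is fully
representable by the basis and detection fails. The parameter is the
single quality-of-filtration knob and is exposed in
`filtration_config()`. The scheme recovers a pure taper to within 1%
and interpolates the baseline across focal lesions (Gaussian widths
1–3 mm, diameter stenoses 30–70%) to within ~2%, as the test suite
asserts. Its known limit: lesions spanning more than roughly a third of
the vessel shade into diffuse disease and cannot be separated from
taper by any single-cutoff filtration.

## The advection term

With leakage, the textbook 1D momentum balance needs care: fluid leaving
through the wall carries its axial momentum with it. Crediting the full
`α ρ d(u²)` difference as pressure recovery (with `u = Q/A` falling
along the vessel because `u ∝ r^{1/3}` under the scaling law) produced
simulated Pd above Pa on healthy tapered vessels — an unphysical vFFR
above 1. The package therefore applies the momentum-correction term in
the form

    ΔP_adv = (α/2) ρ Q̄² Δ(1/A²)

between adjacent healthy nodes, with the axial flow frozen at the
segment mean Q̄. Only calibre-driven velocity change converts to
pressure; leak-induced deceleration does not. α = 4/3 (parabolic
profile) by default; the term can be switched off in `solver_config()`,
and with it off the solver reproduces the closed-form Poiseuille drop to
1e-9 relative. Segment pairs touching a stenosed point are skipped —
kinetic losses there belong to the lumped expansion term.

## Boundary conditions and flow optimisation

Inlet flow is the root of `Pd(Q_in)/Q_in = MVR` inside 50–450 mL/min,
found by bisection of the monotone residual to a relative tolerance of
1e-6; outside the bounds the flow is clamped and flagged. MVR is
referenced to *inlet* flow: the invasive assessment it models
(continuous-thermodilution) measures total vessel flow, and the whole
myocardial territory the vessel feeds — side branches included — drains
the flow that enters it. Referencing the outlet flow instead would,
under the scaling-law leak of a typical taper, demand inlet flows around
500 mL/min at the reference MVR of 361 Wood units — outside the
admissible optimisation window — and push healthy-vessel vFFR far below
the range reported for angiographically normal arteries.

If simulation fails at high flows (severe stenoses), the optimiser first
shrinks to the largest feasible flow and reports either the bracketed
root or, when the MVR target is unreachable before failure, the last
feasible result flagged `"flow limited by simulation failure"`. A
failure at the minimum admissible flow is reported as a failed result.
Failures are always statuses (`failed("negative pressure")`), never
exceptions, so batch completion rates can be accounted per model — the
porosity model, whose leak collapses wherever pressure does, is the most
failure-prone of the leakage family in exactly this mode.

## Tunable parameters

| Parameter | Default | Units | Where | Why |
|---|---|---|---|---|
| `mu` | 0.0035 | Pa·s | `fluid_properties()` | standard blood viscosity; personalised as `0.0014 + 0.0035·hct` when haematocrit is given |
| `rho` | 1050 | kg/m³ | `fluid_properties()` | blood density |
| `n_harmonics` | 4 | — | `filtration_config()` | filtration quality knob (see above) |
| `area_threshold` | 0.80 | — | `filtration_config()` | stenosis definition on area ratio, strict `<` |
| `min_run` | 2 | points | `filtration_config()` | shortest flagged run kept |
| `kt` | 1.52 | — | `stenosis_model_config()` | expansion-loss coefficient of the classical lumped stenosis models |
| `alpha` | 4/3 | — | `solver_config()` | momentum correction, parabolic profile |
| `ptol` | 1e-6 | relative | `solver_config()` | fixed-point pressure tolerance for coupled models |
| `flow_tol` | 1e-6 | relative | `solver_config()` | MVR residual tolerance |
| `q_bounds` | (50, 450) | mL/min | `simulate_vessel()` | admissible inlet-flow window |
| `forchheimer_coefficient` | 0 | Pa/(m²/s)² | `porosity_config()` | quadratic wall-law term, exposed for sensitivity work |

## The synthetic generator

`generate_vessel()` builds tapered profiles (linear, or seeded
piecewise-constant steps mimicking bifurcation calibre changes) with
focal stenoses as Gaussian radius reductions
`r ← r·(1 − DS·exp(−(s−c)²/2w²))`; `w` is the Gaussian standard
deviation in mm. `generate_cohort()` draws geometry from the clinical
reconstruction scales (inlet diameter 2.7 ± 0.5 mm, outlet 1.9 ± 0.4 mm,
clamped at 2 SD), aortic pressure ~N(90, 10) mmHg, haematocrit
~N(0.42, 0.04), and MVR log-normal about a median of 361 Wood units
*scaled by outlet calibre* (`(0.95/r_out)³`, Murray-fashion) — a small
distal bed has high resistance, which is what dimension-personalised
boundary conditions encode. Each case carries a reference FFR from a
2000-point localized-model self-simulation, so cohort statistics have an
internally consistent ground truth.

What the generator does *not* emulate: angiographic reconstruction
error, centreline noise, eccentric or non-axisymmetric lesions, serial
lesions interacting with curvature, or any relationship between lesion
anatomy and microvascular state beyond the calibre scaling. Passing
tests on these cohorts therefore demonstrates internal consistency of
the solver and statistics, not clinical accuracy on real
reconstructions. Under the defaults, unstenosed cohorts land where
angiographically healthy arteries are reported to sit — vFFR roughly
0.85–0.99, none at or below the 0.80 significance threshold — rather
than uniformly above 0.95: with hyperaemic-scale flows, a long small
vessel legitimately loses more than 5% of aortic pressure to friction.

## Numerical choices and degenerate inputs

* Marching is trapezoidal between nodes; the scheme converges at second
  order (verified 200→1600 points against a fixed segmentation).
* Pressure-coupled models iterate leak↔pressure to `ptol`, capped at
  `max_iterations = 100`; conductance starts from the localized
  solution, porosity from uniform Pa. Non-convergence is a failed
  status, not a silent result.
* Porosity calibration fixed-points the budget on the stenosis-free
  geometry to 1e-8 relative, then freezes the conductances for the
  stenosed run.
* The localized weight uses central differences; a step taper
  concentrates its weight on the two nodes spanning the step. If the
  healthy region has no taper at all while the budget is positive, the
  model falls back to the homogenous distribution and flags the result.
* Quantile regression (Bland–Altman lines) minimises the check loss by
  asymmetric iteratively-reweighted least squares polished with
  Nelder–Mead; degenerate pair-mean spread falls back to unconditional
  quantiles, flagged. All-equal differences return exact zero-width
  limits.
* Passing–Bablok excludes pairwise slopes of exactly −1 and offsets the
  median by the count of slopes below −1, the convention that makes the
  estimator symmetric in the two methods.
* ROC orientation is fixed by the clinical reading: lower vFFR is more
  diseased, so "test positive" means score ≤ threshold. Ties contribute
  half, making the trapezoidal AUC equal the Mann–Whitney statistic.
* Geometry validation is strict: non-monotone arc length, non-positive
  radii, or missing columns raise typed errors (`malformed_geometry`,
  `format_error`) before any physics runs.

## Problem sizes in the test suite

The suite exercises 200-point working grids throughout, 2000-point
grids for fine-grid conservation and reference-FFR oracles, cohorts of
12–50 vessels, 2000-pair Monte-Carlo draws for the agreement statistics
and 10,000 replicates for exact-interval coverage — sizes chosen so the
whole suite completes in well under a minute while every stochastic
assertion retains comfortable margins.

## Known limitations

* The five models share one lumped stenosis sub-model; its coefficient
  `kt` is not identifiable from within this package and the default
  (1.52) follows the classical empirical lineage.
* The porosity wall-law parameterisation (taper-derived Darcy term,
  venous reference 0) is this package's concrete realisation of a
  porous-wall leakage function; other parameterisations exist and can
  be explored through `porosity_config()`.
* Filtration cannot separate diffuse disease from taper (a limitation
  of any single-cutoff healthy-lumen estimate), and the stenosis
  threshold of 0.80 is itself a modelling choice with known sensitivity.
* vFFR values are deterministic given geometry and boundary conditions;
  all uncertainty quantification must come from the statistics layer,
  not the solver.
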