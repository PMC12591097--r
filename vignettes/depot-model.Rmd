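---
title: "A mechanistic depot model for intramuscular long-acting injectables with an inflammatory cell layer barrier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A mechanistic depot model for intramuscular long-acting injectables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icldepot)
```

## The problem

Long-acting injectable (LAI) suspensions release drug over weeks to months
from a solid depot injected into muscle. Two processes govern the plasma
profile: dissolution of the suspended particles in the small extracellular
fluid volume at the injection site, and the tissue response to the injected
foreign material. The foreign-body reaction wraps the depot in an
inflammatory cell layer (ICL) — a transient envelope of macrophages and
fibrotic tissue — that acts as a diffusion barrier between the depot fluid
and the circulation. The barrier grows over days, then resolves over weeks;
while it is in place, drug that has already dissolved cannot freely reach the
blood.

`icldepot` implements this picture as an ODE system for aripiprazole lauroxil
(AR-L, the prodrug in the Aristada suspension) and its parent aripiprazole
(AR), and reproduces the workflow used to evaluate it: calibrate the ICL
kinetics on one dose strength, predict the remaining strengths with the same
kinetics, and judge the predictions by fold errors of Cmax and AUC0-t.

## Model structure

The state consists of per-bin solid prodrug masses, the dissolved amount in
the depot fluid, three systemic compartments (amounts of parent drug), and
two bookkeeping integrals (cumulative absorbed, cumulative cleared). All
amounts are in mg, times in hours, concentrations in mg/mL internally and
ng/mL at the interface.

**Dissolution.** The suspension's volume-weighted radius distribution is a
log-normal, either moment-matched to the reported mean ± SD (14.18 ± 7.4 µm)
or quantile-matched to measured Dv10/Dv50/Dv90. A normal family would put
roughly 3% of the mass at negative radii, so the log-normal is used
throughout. The distribution is discretized into `n_bins` (default 20) bins
of equal log-radius width truncated at ±3σ; each bin carries a fixed particle
count and dissolves by the Johnson/Nernst–Brunner film law

$$\frac{dm_i}{dt} = -N_i\,4\pi r_i^2\,\frac{D_{aq}}{h_i}\,
  \max(S_{site} - C_u,\,0), \qquad r_i = r_{0,i}(m_i/m_{0,i})^{1/3},$$

with a 65 µm diffusion layer ($h_i$ constant by default; a `min_radius` rule
capping $h_i$ at the current radius is available, the convention of
radius-coupled Johnson implementations). Exhausted bins are handled by rate
clamping — the smooth $(m/m_0)^{2/3}$ factor vanishes with the mass — rather
than solver events. Going from 20 to 40 bins changes Cmax and AUC by well
under 1%.

The driving concentration $C_u$ is the *unbound* dissolved concentration in
the depot, $C_u = f_{ut}\, A_d / V_{depot}$. With the prodrug's tissue
fraction unbound of 2.25e-8, tissue binding keeps the aqueous phase far from
saturation, which is what lets a compound with 3e-4 mg/mL solubility sustain
months of dissolution-limited release. A consequence worth stating plainly:
the dissolved-but-bound depot pool is an unbounded reservoir (see
*Limitations*).

**Site solubility.** The default dissolution driving solubility is the drug's
reference aqueous solubility (3e-4 mg/mL for the prodrug, measured at pH 7).
This is deliberate: the model's own sensitivity analysis sweeps solubility
over 3e-5–3e-3 mg/mL, log-centered exactly on the reference value, so the
baseline the model family uses at the site *is* the reference solubility.
An ionization-adjusted value can be requested instead by setting `site_ph`
in `depot_physiology()` (Henderson–Hasselbalch scaling for a monoprotic
base, capped by the solubility factor), or overridden outright via
`dissolution_settings(s_site = ...)`.

**Effective depot volume.** The fluid available for dissolution is the
injection volume divided by the muscle extracellular volume fraction 0.118
(e.g. 1.6 mL → 13.6 mL for the 300 mg-equivalent dose).

**ICL barrier.** The layer thickness follows
$\ell(t) = A\,(t - t_{lag})\,e^{-B (t - t_{lag})}$ (zero before the lag):
zero at injection, a single interior maximum $A/(Be)$ at $t_{lag} + 1/B$, and
resolution to zero. Drug permeates the layer as the unbound species, with a
diffusivity of $10^{-5.9514}$ cm²/s (defined for logD(7.4) > 3 only; the
package refuses to guess below that) and a layer fraction unbound
$1/(2.12\,e^{0.523\,\mathrm{logD}(7.4)})$. The layer covers the surface of a
single sphere whose volume is the injected solid mass over a depot density
$\rho$; $\rho$ = 1.774 g/cm³ is back-calculated once from the 400 mg-eq
surface area (2.32 cm²) and then reproduces the 300 and 150 mg-eq areas
(1.92, 1.21 cm²) through the exact dose^(2/3) scaling. The film conductance
is

$$G_{ICL}(t) = \kappa \cdot SA \cdot D_{ICL} \cdot fu_{ICL} / \ell(t)$$

(mL/h; infinite when the thickness is zero). The dimensionless scale $\kappa$
exists because the reference implementation does not publish how these
quantities combine into a permeability; $\kappa$ absorbs that unknown
proportionality and is calibrated together with $A$ and $B$. Note that the
dynamics depend on $A$ and $\kappa$ only through $\kappa/A$ — the pair is a
ridge, deliberately kept because both parameters have distinct physical
readings.

**Egress and disposition.** Perfusion-limited egress acts in series with the
layer: $G_{tot}(t)^{-1} = G_{perf}^{-1} + G_{ICL}(t)^{-1}$ with
$G_{perf} = Q_{depot} R_{bp} / K_p$ and
$Q_{depot} = \text{perfusion} \cdot (V_{depot}/100) \cdot 60$ mL/h. The
outflux is $J = G_{tot}(t)\,(A_d/V_{depot} - \text{backterm})$. For the
prodrug the backterm is zero: systemic esterase cleavage to the parent is
treated as instantaneous and complete, so no prodrug circulates to diffuse
back, and the depot is one-way; the systemic input is $J$ converted by the
molar mass ratio. For a same-species depot (IM solution of the parent) the
backterm is $K_p C_p / R_{bp}$, giving the correct partition-equilibrium
limit. Disposition is the linear three-compartment model with hepatic
clearance from the central compartment (parameters per kg, times a body
weight).

## Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| `A` (ICL magnitude) | cm/h | 2.09e-6 | reference fitted value; free in calibration |
| `B` (ICL decay rate) | 1/h | 0.012 | reference fitted value; free in calibration |
| `t_lag` (ICL onset) | h | 0 | reference fitted value |
| `kappa` (conductance scale) | – | 1 | unknown flux proportionality; free in calibration |
| `h_uwl` (diffusion layer) | µm | 65 | fitted value for this suspension |
| mean radius ± SD | µm | 14.18 ± 7.4 | measured particle size |
| `n_bins` | – | 20 | metrics stable to <1% vs 40 bins |
| `s_site` | mg/mL | 3e-4 (prodrug) | reference solubility; sensitivity-analysis baseline |
| `kp`, `fut` (prodrug) | – | 4.28, 2.25e-8 | partitioning inputs, taken as given |
| perfusion | mL/min/100 g | 9.6 | geometric center of the 4.8–19.2 sweep range |
| `ecf_fraction` | – | 0.118 | muscle extracellular volume fraction |
| body weight | kg | 70 | not part of the published parameter set; generic adult default, configurable |
| horizon | h | 2136 (suspension) | 89-day observation window; AUC0-t is computed to the horizon because clinical sampling windows are not published |
| `rtol`, `atol`, `dt` | –, mg, h | 1e-8, 1e-12, 1 | stiff-safe tolerances; dense output |

## Calibration and validation

`fit_icl()` minimizes a weighted least-squares objective with bounded
Levenberg–Marquardt: squared relative errors of Cmax, AUC0-t and Tmax for a
metrics target (weights 1, 1, 0.5 — Tmax is coarsely observable on clinical
grids), or squared log-residuals for a profile target. Positive parameters
spanning orders of magnitude (`A`, `B`, `kappa`, `h_uwl`) are fitted in log
space; bounds default to the sensitivity-analysis ranges. Optimization is
fully deterministic: a fixed grid of three log-spaced interior points per
free parameter is screened by objective value, local optimization runs from
the best five starts, and the best optimum is returned. The finite-difference
step of the numeric Jacobian is widened (`epsfcn = 1e-6`) so ODE-solver noise
does not corrupt the derivatives.

`run_validation_workflow()` chains the whole study design: fit
(`A`, `B`, `kappa`) to the 400 mg-equivalent observed metrics, re-simulate
all three strengths with the fitted kinetics and dose-specific geometry
(injection volume, depot volume, spherical surface area), and tabulate fold
errors with 25%-band flags. The workflow uses a 2 h output grid — the
deterministic pipeline then takes about two minutes, with metric changes well
under a percent relative to a 1 h grid.

On the packaged observed data the calibrated model lands at fold errors of
about 1.24 (Cmax) and 1.16 (AUC0-t) at 400 mg, 1.03/1.31 at 300 mg and
1.11/1.14 at 150 mg, a maximum deviation of roughly 31% — just outside the
25% band, driven by the 300 mg AUC row. Two structural facts explain this
and are worth knowing before using the model for prediction:

1. **A Cmax floor.** Because the barrier gates egress of a total (largely
   tissue-bound) depot concentration while dissolution remains sink-like,
   drug dissolved during the ICL window accumulates in the depot and is
   released as the layer thins. For every admissible `(A, B, kappa)` the
   simulated 400 mg Cmax stays at or above the no-ICL value (~120 ng/mL on
   the calibrated grid), so an observed Cmax below that floor cannot be fitted
   exactly. The calibration lands on the slowest admissible layer decay
   (`B` at its 0.003 1/h bound) to flatten the profile as much as the bounds
   allow.
2. **Dose-normalized exposure is nearly linear.** Geometry gives mild
   sub-linearity (surface area grows as dose^(2/3)), but predicted AUC0-t per
   mg is almost constant across 150–400 mg. The observed 300 mg AUC0-t is
   about 11% lower per mg than the 400 mg row; a model fitted to the 400 row
   at AUC fold error ~1.16 therefore cannot land the 300 row inside 25%.

Freeing the diffusion-layer thickness together with the ICL kinetics
(`fit_icl(..., free = c("A", "B", "kappa", "h_uwl"))` — the thickness was
itself originally fitted to the same 400 mg data) removes most of the misfit;
the packaged validation workflow keeps it fixed at 65 µm to keep the
calibration and validation roles of the inputs cleanly separated.

## Synthetic data

`generate_synthetic_profile()` emulates an observed concentration–time
profile: the model's own output sampled on a clinical-style grid and
multiplied by log-normal noise with unit mean
(`exp(N(-sigma^2/2, sigma^2))`, `sigma^2 = log(1 + cv^2)`), reproducible
under a fixed seed, with the global RNG stream restored afterwards. It
emulates multiplicative assay/biological scatter around a smooth mean
profile. It does **not** emulate inter-individual variability (one set of
parameters generates the mean), sparse-sampling censoring, values below the
quantification limit, or dose-group differences in sampling design — so
parameter-recovery results (A and B recovered with ≤15% median error from 20
replicates at 10% CV in the test suite) say the estimator is well-behaved on
clean single-subject-like data, not that clinical estimation of ICL kinetics
is this precise.

## Numerical choices

* `deSolve::lsoda` with `rtol = 1e-8`, `atol = 1e-12` mg; the mass-balance
  residual (dose vs solids + dissolved + body + cleared, in parent
  equivalents) is checked at every output time and is ~1e-14 in practice.
* Negative states beyond 1e-6 of the dose abort with a diagnostic; tiny
  solver-level negatives are clamped in rate evaluations
  (`max(m, 0)^{2/3}`).
* Cmax/Tmax are read off the dense output grid (first time attaining the
  maximum on plateaus); AUC is the linear trapezoid on that grid —
  simulated output is dense, so log-trapezoid machinery would add nothing.
* The conductance at zero thickness is `Inf` and the series combination
  reduces exactly to the perfusion conductance, so `A = 0`, `t < t_lag` and
  `enabled = FALSE` are all the same no-barrier limit.
* `kappa = 0` cleanly blocks the depot (zero exposure, mass still conserved).

## Limitations

* The egress flux law (total-concentration driving force behind a series
  barrier) is the package's reading of an unpublished implementation; the
  two structural consequences above are its fingerprint. A solubility-capped
  barrier flux would behave differently (particle-size-insensitive while the
  layer is up) but contradicts the conductance formulation adopted here.
* Single dose only; no repeat dosing, no population variability.
* No injection-site precipitation, oedema, lymphatic uptake or
  macrophage-mediated secondary depots; the ICL is a lumped film, not
  mechanistic immunology.
* Oral absorption and first-pass extraction are out of scope; disposition
  parameters are inputs, not fitted here.
* `t_lag`, `A`, `B` are assumed dose-independent (same formulation, same
  tissue response) — the central untested assumption of the approach.

## A worked example

```{r example, eval = FALSE}
sc <- scenario_aristada(400)            # 400 mg-eq suspension, ICL on
sim <- simulate_scenario(sc)
pk_metrics(sim)
#> Cmax 145.2 ng/mL | Tmax 277 h | AUC0-2136 161896 ng*h/mL

no_icl <- simulate_scenario(scenario_aristada(400, icl = FALSE))
pk_metrics(no_icl)
#> Cmax 131.9 ng/mL | Tmax 252 h | AUC0-2136 161985 ng*h/mL

wf <- run_validation_workflow()         # ~2 min, deterministic
wf$table[, c("dose_mg_eq", "cmax_fe", "auc0t_fe")]
#>   dose_mg_eq cmax_fe auc0t_fe
#> 1        150   1.113    1.139
#> 2        300   1.031    1.306
#> 3        400   1.237    1.157
```
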