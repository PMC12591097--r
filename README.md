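# icldepot

Mechanistic pharmacokinetic simulation of intramuscular long-acting
injectable (LAI) depots, with an inflammatory cell layer (ICL) diffusion
barrier.

## What it is for

When a drug suspension is injected into muscle, the plasma profile over the
following weeks is shaped by two things: dissolution of the suspended
particles in the small extracellular fluid volume at the injection site, and
the foreign-body reaction — a transient layer of inflammatory cells that
envelops the depot and impedes diffusion of dissolved drug into the
circulation. `icldepot` is for modellers and formulators who want to simulate
that interplay, calibrate the tissue-response kinetics against observed
pharmacokinetics of one dose strength, and test whether the same kinetics
predict the other strengths. It ships ready-made scenarios for aripiprazole
lauroxil (AR-L, the prodrug in the Aristada suspension: 150/300/400 mg
aripiprazole-equivalent IM doses) plus aripiprazole IM-solution and
IV-infusion dosing.

## The model

State: per-bin solid prodrug masses `m_i`, dissolved depot amount `A_d`,
three systemic compartments of parent drug, and cumulative
absorbed/cleared ledgers.

* **Johnson-type polydisperse dissolution.** A log-normal volume-weighted
  radius distribution (default 14.18 ± 7.4 µm) is split into 20 bins; each
  bin dissolves by the film law
  `dm_i/dt = −N_i 4π r_i² (D_aq/h) max(S_site − C_u, 0)` with
  `r_i = r_0i (m_i/m_0i)^(1/3)`, a 65 µm diffusion layer, and the unbound
  depot concentration `C_u = f_ut A_d / V_depot` as the back-pressure
  (tissue binding keeps dissolution sink-like).
* **ICL barrier.** Thickness `ℓ(t) = A (t−t_lag) e^(−B(t−t_lag))`; drug
  crosses as the unbound species with diffusivity `10^-5.9514` cm²/s and
  layer fraction unbound `1/(2.12 e^(0.523 logD7.4))`, over the surface of a
  sphere of volume dose/ρ. Conductance
  `G_ICL(t) = κ · SA · D_ICL · fu_ICL / ℓ(t)` (mL/h), with κ a calibrated
  scale for the unpublished flux proportionality.
* **Egress.** Perfusion/partition-limited transfer `G_perf = Q_depot R_bp/Kp`
  in series with `G_ICL`; outflux `J = G_tot (A_d/V_depot − backterm)`. The
  prodrug is cleaved to parent instantly on absorption (one-way depot,
  molar-mass conversion of the input).
* **Disposition.** Linear three-compartment model with hepatic clearance
  (V_c 1.5825 L/kg, CL_H 0.03028 L/h/kg, k12/k21/k13/k31 as published),
  plasma concentration in ng/mL.

Validation arithmetic follows the field convention: fold error
FE = simulated/observed per metric, accepted when |FE − 1| ≤ 25%.

## Worked example

```r
library(icldepot)

sim <- simulate_scenario(scenario_aristada(400))      # ICL on
print(sim)
#> <lai_simulation> aripiprazole lauroxil, 400 mg parent-eq (im_suspension)
#>   Cmax 145.2 ng/mL at Tmax 277 h | AUC0-2136 161896 ng*h/mL
#>   mass-balance residual 2.52e-14 (relative)

pk_metrics(simulate_scenario(scenario_aristada(400, icl = FALSE)))
#> Cmax 131.9 ng/mL | Tmax 252 h | AUC0-2136 161985 ng*h/mL
```

With the default (uncalibrated, κ = 1) layer the barrier delays the peak
(Tmax 277 vs 252 h) while total exposure is conserved. The full
calibrate-then-validate workflow — fit (A, B, κ) to the 400 mg-eq observed
Cmax/AUC0-t/Tmax, then predict all strengths with the same kinetics and
dose-specific geometry — is one call (~2 min, deterministic):

```r
wf <- run_validation_workflow()
wf$table[, c("dose_mg_eq", "cmax_obs", "cmax_sim", "cmax_fe",
             "auc0t_obs", "auc0t_sim", "auc0t_fe")]
#>   dose_mg_eq cmax_obs cmax_sim cmax_fe auc0t_obs auc0t_sim auc0t_fe
#> 1        150    40.66    45.25   1.113     52810     60152    1.139
#> 2        300    87.61    90.36   1.031     91910    119996    1.306
#> 3        400    97.39   120.46   1.237    138100    159794    1.157
```

Cmax is predicted within 4–24% and AUC0-t within 14–31%; the 300 mg AUC row
sits outside the 25% band — the methods vignette
(`vignettes/depot-model.Rmd`) explains the two structural reasons (a Cmax
floor from the dissolved-depot reservoir, and near-linear dose-normalized
exposure) and what they imply for interpretation.

Scenarios can also be loaded from strict, unit-annotated JSON configs
(`load_scenario("arl_im_400")` or a file path), profiles written to CSV with
`write_profile()`, and one-at-a-time sensitivity sweeps run with
`psa_sweep(base, "icl.A", from = 2.09e-8, to = 2.09e-4)`.

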