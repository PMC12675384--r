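# pedotherm

Quantify how the sole of the foot heats up during a walk, and why.

Plantar skin temperature rises by several degrees over a 30-minute walk,
and impaired regulation of that rise is linked to foot complications
(e.g. ulceration in diabetes). Two mechanisms contribute: **mechanical**
heating — the net work dissipated by foot structures each stride — and
**physiological** exchange — skin blood flow, sweating, conduction and
convection. `pedotherm` is an R package for researchers in thermal
physiology and biomechanics that takes thermal images of the plantar
surface through to a quantitative partition of the temperature rise into
those two contributions.

## What it computes

1. **Regional extraction.** From a thermal frame (pixel matrix, °C) and a
   manual-segmentation label mask (hallux, MTP, midfoot, arch, heel),
   per-region mean temperatures and pixel areas, and the area-weighted
   whole-foot temperature
   `T_foot(t) = Σ A_r(t) T_r(t) / Σ A_r(t)`.
2. **Temporal models.** Each series is fit with a line `T = m t + b` and a
   six-parameter generalized logistic (Richards) curve
   `T(t) = A + (K − A) / (C + Q e^(−B t))^(1/ν)`
   via Levenberg–Marquardt least squares, compared by
   `MSE = SS_res/(n − p)` and `S_res = sqrt(MSE)`.
3. **Thermodynamic partition.** Per-stride heating
   `ΔT_stride = −W_stride / (m_foot c_foot)` accumulated over the stride
   schedule gives `ΔT_mech(t)`; the physiological contribution is the
   residual `ΔT_phys(t) = ΔT_exp(t) − ΔT_mech(t)`, with envelopes from
   work and specific-heat bounds, and an extrapolated crossing time of the
   43.3 °C first-degree-burn threshold.
4. **Synthetic cohorts.** A seeded generator (regional logistic ground
   truth + Gaussian noise, plus matching frames and masks) for testing and
   simulation studies.

## Worked example

```r
library(pedotherm)

params <- thermo_params(W_stride = -0.0034,  # kJ per stride (net dissipation)
                        m_foot = 1.17,       # kg
                        c_foot = 1.96,       # kJ/(kg K)
                        total_strides = 1674, duration_min = 30,
                        W_bounds = c(-0.0071, 0.00023),
                        c_bounds = c(1.31, 3.62))

mech <- mechanical_curve(params)
tail(mech$dT, 1)
#> [1] 2.481947

exp_df <- data.frame(time_min = seq(0, 30, 5),
                     delta_C = 3.50 * seq(0, 30, 5) / 30)  # observed rise
dec <- decompose_series(exp_df, mech)
dec$table[7, ]
#>   time_min dT_exp  dT_mech  dT_phys
#> 7       30    3.5 2.481947 1.018053

burn_time(baseline_C = 30, mech_rate_per_min = tail(mech$dT, 1) / 30)
#> Time to exceed 43.3 degC from 30.0 degC (mechanical_only): 160.8 min

walk_distance_km(160)   # at the default 1.25 m/s
#> [1] 12
```

Reading: of a 3.50 °C whole-foot rise over the walk, about 2.5 °C is
attributable to mechanical work dissipation and about 1.0 °C to
physiology; mechanical heating alone from a 30 °C baseline would take
~2.7 h of continuous walking (~12 km) to reach the burn threshold,
suggesting physiological regulation, not mechanics, dominates thermal
safety.

End-to-end on synthetic data:

```r
cohort <- generate_cohort(synthetic_config(seed = 42))
fm <- cohort$participants[[1]]$frames[[1]]
stats <- extract_region_stats(fm$frame, fm$mask)
whole_foot_temperature(stats)

s <- cohort$participants[[1]]$series$hallux
compare_models(fit_linear(s), fit_logistic(s))
```

A config-driven pipeline (`run_simulate`, `run_extract`, `run_fit`,
`run_partition`, `run_all`) and a thin CLI (`inst/cli/pedotherm.R`) wrap
the same functions; see `?read_pipeline_config`.

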