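# apsens

Gaussian-process emulation and variance-based sensitivity / uncertainty
analysis of human atrial action-potential models.

## What it does

Detailed cardiac myocyte models — here the **Courtemanche** and
**Maleckar** human atrial models — map dozens of uncertain parameters
(channel conductances, pump rates, calcium-handling constants, cell
capacitance, extracellular concentrations) to the shape of the action
potential and calcium transient. `apsens` quantifies that map globally:

1. **Design**: maximin Latin-hypercube samples over each model's input
   space, every input normalized to [0, 1] over `central × (1 ± f)`
   ranges (f = 0.5 for most inputs, 0.25 for G_K1 and C_m, 0.10 for
   extracellular concentrations).
2. **Simulation**: stiff adaptive integration (lsoda, rtol = atol =
   1e-6, max step 0.5 ms) of 40 paced beats at a cycle length of
   1000 ms, with compiled right-hand sides; S1–S2 protocols for
   restitution. Runs showing pacemaking, a resting potential above
   −60 mV, APD90 above 600 ms, or >5% APD alternans are excluded.
3. **Biomarkers**: eleven outputs per run — dV/dt_max, V_max, V_20..V_80,
   APD_50, APD_90, RestVm, Ca_min, Ca_max.
4. **Emulation**: one Gaussian process per output, linear mean
   m(x) = β₀ + Σ β_p x_p plus a zero-mean GP with squared-exponential
   correlation c(x,x′) = exp[−Σ_p (x_p−x′_p)²/δ_p²], trained by
   restricted (weak-prior) maximum likelihood with 10 restarts and a
   fixed 1e-7 nugget; validated by MAPE and the median individual
   standard error (ISE) on held-out runs.
5. **Sensitivity & uncertainty**: closed-form first-order and
   total-effect Sobol indices under independent Gaussian input measures,

   S_w = Var[E(f(x)|x_w)] / Var[f(x)],
   S_Tw = (Var[f(x)] − Var[E(f(x)|x_~w)]) / Var[f(x)],

   signed by the main-effect gradient at the central value, verified
   against a Monte-Carlo pick-freeze oracle; plus uncertainty
   propagation, standardized multivariate regression indices (S ≈ B²),
   APD restitution surfaces, and a PCA summary of output
   dimensionality.

A closed-form **toy action-potential generator** with known biomarker
values and monotone parameter effects makes the entire pipeline testable
in seconds.

## Worked example

A Stage-1 analysis of the toy model (seconds; swap in
`"courtemanche"` with the default 300/150 runs for the real thing):

```r
library(apsens)
cfg <- stage_config("toy", 1, n_design = 80, n_validation = 40,
                    cl = 600, n_beats = 4, seed = 7, restarts = 4)
res <- run_stage(cfg)
glance(res)
#>   model stage n_design n_kept n_excluded worst_mape worst_median_ise
#> 1   toy     1       80     80          0      0.671             1.41

res$sensitivity |> dplyr::filter(output == "APD_90") |>
  dplyr::arrange(dplyr::desc(S)) |> head(3)
#>        input        S      S_T sign  S_signed interaction
#> 1  apd_scale  1.0e+00  1.0e+00    1   1.0e+00     3.9e-05
#> 2  rest_coef  1.2e-04  1.6e-04   -1  -1.2e-04     3.9e-05
#> 3  upstroke_slope 1.6e-05 1.6e-05 -1 -1.6e-05    1.3e-07
```

The constructed APD-scale parameter absorbs the APD90 variance with a
positive sign, and the emulators reproduce the held-out toy runs to a
fraction of a percent (MAPE).

The targeted verification experiment on the real models:

```r
gkur_experiment("courtemanche")$apd   #   level APD_90
                                      #     0.5  285.8
                                      #     1.0  293.5
                                      #     1.5  294.1
gkur_experiment("maleckar")$apd       #     0.5  209.2
                                      #     1.0  182.7
                                      #     1.5  168.1
```

Halving the ultra-rapid K⁺ conductance *lengthens* the Maleckar action
potential by ~27 ms but slightly *shortens* the Courtemanche one —
opposite directions, because the two models balance I_CaL and I_Kr
differently during the plateau. `write_stage_bundle()` exports every
table (designs, biomarkers, exclusions, validation, signed indices,
main effects, regression coefficients) as CSV plus JSON-serialized
emulators.

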