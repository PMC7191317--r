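---
title: "Emulator-based sensitivity and uncertainty analysis of atrial myocyte models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emulator-based sensitivity and uncertainty analysis of atrial myocyte models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apsens)
```

## The problem

Biophysically detailed models of the cardiac action potential are systems
of stiff, nonlinear ODEs with dozens of parameters: maximum channel
conductances, pump and exchanger rates, calcium-handling constants, cell
capacitance, extracellular ion concentrations. Many of these quantities
are not physical constants — they vary from cell to cell and over time —
yet how their uncertainty propagates to the action potential is hard to
see from the equations. `apsens` quantifies it for two widely used human
atrial myocyte models: the Courtemanche model and the Maleckar extension
of the Nygren model. The approach is a two-stage, emulator-based global
sensitivity analysis:

1. sample the parameter space with a space-filling design and simulate
   the cell model for each draw;
2. summarize each simulated run by a panel of eleven biomarkers of the
   action potential and calcium transient;
3. train one Gaussian-process (GP) emulator per biomarker on the
   design data;
4. compute variance-based first-order and total-effect sensitivity
   indices, main-effect curves, and output uncertainty from the
   emulators, which are fast enough to integrate where the simulator is
   not.

A second stage repeats the analysis on the handful of inputs that
dominate action-potential shape and duration, adding the diastolic
interval of a premature (S2) beat as an input so that rate dependence
(APD restitution) can be emulated as well.

## Simulators

`simulate_ap()` integrates the Courtemanche (21 states, time in ms) or
Maleckar (29 states, time in s internally) model with `deSolve::lsoda`,
at `rtol = atol = 1e-6` and a maximum step of 0.5 ms, the settings under
which the biomarkers are converged to well under a milli­second of APD
(see the solver-convergence test). Two stability modifications are
built in: the Courtemanche intracellular Na\\(^+\\) and K\\(^+\\)
concentrations are clamped at 11.17 and 139.00 mM (removing their slow
drift), and the Maleckar acetylcholine-activated K\\(^+\\) current is
zero. Stimuli are square current pulses — 2000 pA for 2 ms
(Courtemanche) and 750 pA, i.e. a density of 750/C\\(_m\\) pA/pF, for
6 ms (Maleckar) — applied by integrating each beat piecewise, so pulse
edges land exactly on segment boundaries rather than being found by the
step controller.

Runs start from the published initial conditions (cold start: each
design run is independent, not continued from a neighbour) and are paced
for 40 beats at a cycle length of 1000 ms; the final beat is analyzed.
S1–S2 runs use 39 S1 beats; the S2 stimulus is delivered at the final S1
onset plus that beat's APD90, plus a 10 ms guard offset, plus the
requested diastolic interval. Anchoring the interval at repolarization
(rather than at the S1 stimulus) keeps "DI" meaning what it says: the
recovery time before the premature beat.

The compiled right-hand sides are verified in the test suite against an
independent R transcription of each equation set, and against the
published resting potentials and APDs (about −81 mV / 300 ms for
Courtemanche, −78 mV / 180 ms for Maleckar at this pacing).

## Input spaces and design

`build_input_space()` defines the inputs: 20 for Courtemanche, 22 for
Maleckar. Ranges are `central × (1 ± f)` with `f = 0.5` for most inputs,
0.25 for G\\(_{K1}\\) and C\\(_m\\), and 0.10 for the extracellular
concentrations — narrower where wide variation produces mostly
unphysiological runs. All analysis happens on the normalized `[0, 1]`
scale (`normalize_inputs()`), so indices are comparable across inputs
with very different units. One printed-range audit trail lives in
`inst/extdata/table1_printed_ranges.csv`: a few published endpoint
values are internally inconsistent with their percentage rule, and this
package derives every range from the percentage, which is the
self-consistent reading. The Courtemanche SR release rate constant is
taken at its published model default of 30 ms\\(^{-1}\\).

Designs are maximin Latin hypercubes: `latin_hypercube()` draws a pool
of candidate LHC samples (default 50) and keeps the one with the largest
minimum pairwise distance. The criterion is the simplest defensible
reading of an "optimized" LHC and is fully seeded.

Stage 2 keeps the eight (Courtemanche) or seven (Maleckar) inputs whose
Stage-1 first-order index on shape/duration outputs exceeds 0.1, fixes
everything else at the central value, and adds DI with range 50–450 ms.

## Biomarkers and the plausibility filter

Eleven outputs summarize each run: maximum upstroke slope, peak voltage,
voltages at 20/40/60/80% of APD90, APD50 and APD90, resting potential
(mean voltage over a 10 ms window ending 100 ms before the upstroke),
and the calcium-transient minimum and maximum over the final beat's
cycle. APD\\(_x\\) is measured from the activation time (maximum dV/dt
inside the stimulus window) to the first crossing of
\\(V_{max} - x\\% (V_{max} - RestV_m)\\), with linear interpolation
between samples — an amplitude-fraction convention anchored to each
beat's own peak and rest. Level crossings use linear interpolation
because the solver output is dense (0.5 ms), making higher-order
interpolation unnecessary.

Runs enter the design data only if they pass a plausibility filter:
no spontaneous (pacemaking) upstrokes outside stimulus windows, resting
potential at or below −60 mV, APD90 at or below 600 ms (failure to
repolarize counts as a long APD), and no alternans — the final pair of
S1 beats must agree in APD90 to within 5%, measured relative to the
later beat. The resting-potential and APD criteria are judged on the
final S1 beat. For plain S1 pacing that is the analysis beat itself;
for S1–S2 runs the distinction matters: at short diastolic intervals
the 10 ms window 100 ms before the premature upstroke overlaps the
previous beat's repolarization tail, so a "resting" potential measured
there is elevated by design, not by pathology. Judging plausibility on
the paced train keeps the filter about the model's behavior, and with
it the Stage-2 design spaces produce no exclusions at all. Pacemaking detection treats as an upstroke any contiguous
run of samples with dV/dt ≥ 5 mV/ms whose excursion exceeds 10 mV; a
window of 50 ms after each stimulus separates paced from spontaneous
events. These two detection constants are not part of the published
filter; they were chosen once to separate genuine upstrokes from plateau
dynamics in both models and are exposed as arguments of
`detect_activations()`.

## The emulator

Each output gets its own GP with a linear mean
\\(m(x) = \beta_0 + \sum_p \beta_p x_p\\) and squared-exponential
correlation
\\(c(x, x') = \exp[-\sum_p (x_p - x'_p)^2 / \delta_p^2]\\).
Training uses the weak-prior (Kennedy–O'Hagan) treatment: a flat prior
on \\(\beta\\) and a Jeffreys-type prior on \\(\sigma^2\\) are
integrated out analytically, leaving a restricted marginal likelihood in
the length scales \\(\delta\\) alone. `gp_train()` maximizes it with
L-BFGS-B on \\(\log\delta\\) using the analytic gradient, restarting ten
times from length scales drawn log-uniformly on `[0.1, 10]` and keeping
the best restart; the restart log is stored on the fitted object. A
fixed nugget of \\(10^{-7}\\) stabilizes the Cholesky factorization —
the simulator is deterministic, so no noise variance is estimated.
Length scales are bounded above at five input ranges: beyond that the
likelihood is flat (the kernel factor of such an input is effectively
constant over the unit cube), while unbounded scales drive the
correlation matrix toward singularity and the closed-form sensitivity
integrals into catastrophic cancellation, so the bounded optimum is the
statistically equivalent, numerically well-posed representative.
Outputs are standardized to zero mean and unit variance before training
and de-standardized on prediction; validation metrics are computed on
the original scale, so the standardization is invisible to the user.
Two numerical floors keep degenerate cases well defined: when an output
is captured exactly by the linear mean (the toy model's upstroke slope,
for instance), the residual quadratic form is floored at rounding level
rather than allowed to go negative.

Validation (`gp_validate()`) reports MAPE — the mean absolute
prediction error as a percentage of the validation-set mean, a
denominator chosen to avoid instability when individual outputs are
near zero — and the individual standard error, the absolute error
divided by the posterior predictive *standard deviation*. The printed
definition of the latter divides by the variance; since the quantity is
called a standard error and is judged against 1.0, the
standard-deviation form is the unit-consistent one and is the default,
with the variance form available via `ise_form = "variance"`.

## Sensitivity and uncertainty analysis

Indices are computed under independent Gaussian measures on the
normalized inputs: mean 0.5, variance 0.02 for the ±50% inputs, 0.04
for G\\(_{K1}\\) and C\\(_m\\), 0.1 for the extracellular
concentrations. These are untruncated Gaussians — with variance 0.1 a
substantial fraction of the mass lies outside `[0, 1]`; that is the
convention of the source analysis, and it is what makes the integrals
closed-form. The indices are computed on the emulator posterior mean;
the emulator's own predictive variance is reported separately
(`output_uncertainty()$emulator_var`) rather than folded into the
variance decomposition.

For a GP posterior mean (linear mean + kernel smoother), every integral
needed for
\\(S_w = \mathrm{Var}[E(f \mid x_w)]/\mathrm{Var}[f]\\) and
\\(S_{Tw} = 1 - \mathrm{Var}[E(f \mid x_{\sim w})]/\mathrm{Var}[f]\\)
factorizes into one-dimensional Gaussian integrals of the kernel with
closed forms (`sobol_indices()` evaluates them in the log domain to
avoid underflow of the pairwise products). A brute-force Monte-Carlo
oracle (`mc_oracle()`, Saltelli first-order and Jansen total-effect
pick-freeze estimators with standard errors) verifies the analytic path;
the test suite requires agreement within three MC standard errors on
twenty randomized emulator fixtures, and exact recovery on linear and
pure-interaction functions where the decomposition is known by hand.

Because an index is a ratio of variances it carries no direction, so
each index is signed by the gradient of its main-effect curve —
\\(E[f \mid x_w = g]\\) on the grid `0, 0.01, ..., 1` — across the grid
points adjacent to the central value 0.5; a zero gradient leaves the
index unsigned (sign 0). The difference \\(S_{Tw} - |S_w|\\) is reported
as the interaction contribution of each input.

`restitution_surface()` evaluates a Stage-2 APD90 emulator over a
DI × second-input grid with all other inputs fixed at 0.5 and no input
uncertainty, so its 95% band (mean ± 1.96 posterior sd) reflects
emulator uncertainty only. `uncertainty_sweep()` recomputes the output
mean and variance as a common input standard deviation grows, at input
means 0.4, 0.5 and 0.6.

## The toy model and what passing tests show

`simulate_toy_ap()` is a closed-form, piecewise-linear action-potential
generator: parameters set the upstroke slope, peak, plateau, resting
potential, APD scale, calcium extremes, and an exponential APD-DI
restitution. Every biomarker is an analytic function of the parameters
(`toy_biomarkers()`), and each parameter acts monotonically on its
primary biomarker, so extraction accuracy, filter behavior, dominant-
input recovery, and sign assignment all have unambiguous ground truth,
and the whole pipeline runs in seconds. The toy model emulates the
statistical structure the analysis assumes — a smooth deterministic
map from a hypercube to biomarkers — and nothing else: it has no
channel kinetics, no current interactions, and its outputs are nearly
additive in its parameters. Toy-based tests therefore validate the
machinery (design, extraction, emulation, integration, bookkeeping),
while the fidelity of the science rests on the two biophysical models
and their own checks.

## Problem sizes and numerical choices

The workflow-level checks and the reproduction script use a 300-run
Stage-1 Courtemanche design with 60 held-out validation runs, a 200-run
Stage-2 design, and 10 training restarts per output — the design sizes
of the original two-stage analysis, with a validation set large enough
that at least 50 runs survive the filter. A 40-beat run integrates in
about half a second, a Stage-1 emulator trains in about 15 s, and the
closed-form index computation is negligible, so the full Stage-1
workflow completes in roughly ten minutes on one core.

Other fixed choices: traces are sampled every 0.5 ms (matching the
maximum solver step; the reported upstroke slope is therefore the
discrete-grid slope); S2 onsets are rounded to the output grid; the
alternans denominator is the final beat; Ca extremes are taken over the
final beat's cycle rather than the whole run; ties in the main-effect
gradient give sign 0. The heatmap display thresholds used in published
figures (hide |S| < 0.05 or total effects < 0.01) are presentation
options of `plot_sensitivity_heatmap()` inputs, never applied to stored
results.

## Known limitations

The analysis inherits the scope of its design ranges: the emulators say
nothing about parameter regions outside `central × (1 ± f)`, and the
filter deliberately removes the most extreme behaviors, so the input
regions that *cause* pacemaking or alternans are not modeled — their
locations are only recorded in the exclusion report. Single-output GPs
ignore correlation between biomarkers (a principal-component analysis
of the output matrix, `pca_outputs()`, shows about six components carry
95% of the Courtemanche output variance, so a reduced multi-output
emulation would be possible). Only first-order and total-effect indices
are computed; pairwise indices are not. The Gaussian input measure is a
modeling convention, not a claim about biological parameter
distributions.

## A worked example at toy scale

```{r toy-example, eval = FALSE}
cfg <- stage_config("toy", 1, n_design = 80, n_validation = 40,
                    cl = 600, n_beats = 4, seed = 7, restarts = 4)
res <- run_stage(cfg)
glance(res)
res$sensitivity |>
  dplyr::filter(output == "APD_90") |>
  dplyr::arrange(dplyr::desc(S))
```

The APD-scale parameter attains a first-order index of essentially 1 on
APD90 with positive sign, as constructed. Swapping `"toy"` for
`"courtemanche"` (and the Stage-1 defaults of 300/150 runs) gives the
full biophysical analysis; `gkur_experiment()` then reproduces the
targeted verification that lowering the ultra-rapid K\\(^+\\)
conductance lengthens the Maleckar action potential but slightly
shortens the Courtemanche one — the two models balance their plateau
currents differently, and the emulator main effects predict exactly
this divergence.
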