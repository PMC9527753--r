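---
title: "Modelling and fitting small-molecule–DNA binding kinetics from fluorescence sensorgrams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and fitting small-molecule-DNA binding kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(switchkin)
```

## The measurement and the model

switchSense-style biosensors tether short DNA duplexes ("nanolevers") to a
gold chip surface; a fluorophore at the free end reports, in real time, the
binding of a small-molecule analyte flowing over the chip as a percent
change in fluorescence. A measurement cycle has three phases: a baseline
with buffer only, an *association* phase while analyte solution flows, and
a *dissociation* phase after switching back to buffer. One experiment
records such a cycle at each concentration of a descending dilution ladder,
bracketed by zero-concentration blank runs.

`switchkin` models each trace with the standard 1:1 interaction
(pseudo-first-order Langmuir) model. During association the fractional
occupancy relaxes toward its equilibrium with the composite rate
$k_\mathrm{obs} = k_a c + k_d$, giving

$$F(t) = y_0 + A\left(1 - e^{-(k_a c + k_d)(t - t_a)}\right), \qquad t_a \le t < t_d,$$

and during dissociation

$$F(t) = y_0 + A_d\left(f_\mathrm{res} + (1 - f_\mathrm{res})\,e^{-k_d (t - t_d)}\right), \qquad t \ge t_d,$$

where $A$ is the per-trace signal amplitude (%), $y_0$ the per-trace
baseline (%), $t_a$ and $t_d$ the phase start times (s), $c$ the molar
analyte concentration, $k_a$ (M⁻¹s⁻¹) and $k_d$ (s⁻¹) the association and
dissociation rate constants. At equilibrium the association constant is
$K_A = k_a / k_d$ and the dissociation constant its reciprocal,
$K_D = k_d/k_a$; the package always derives both from the fitted rates, so
$K_A K_D = 1$ holds exactly.

$f_\mathrm{res} \in [0,1]$ is a *residual bound fraction* extending the
model to analytes whose signal does not return to baseline under buffer
flow (incomplete dissociation): the decay plateaus at
$y_0 + A_d f_\mathrm{res}$ instead of $y_0$. Setting $f_\mathrm{res}=0$
recovers the plain complete-dissociation decay exactly.

Two choices here were genuinely open and are worth recording:

* **Dissociation amplitude.** `model_trace()` pins $A_d$ to the association
  signal at $t_d$ (minus baseline), so the noise-free model is continuous at
  the phase boundary. Real measured curves are continuous there, which is
  the physical ground for the default; a free $A_d$ is only meaningful for
  truncated records and is not fitted by default.
* **Blanks.** A zero-concentration trace is modelled as a flat baseline:
  without analyte nothing binds, so the amplitude term does not apply.
  Blanks never enter the fit; they feed `blank_correct()`, which subtracts
  the pointwise mean of the available blanks (interpolated onto each
  analyte trace's grid) and removes them, making the operation idempotent.

## What the generator emulates — and what it does not

`simulate_series()` produces one noisy trace per concentration of a
`series_design()`, plus leading/trailing blanks. Its defaults encode the
standard measurement conditions for the systems the package targets:

* fast intercalator (ethidium-bromide-like), `design_eb_standard()`:
  five concentrations from $10^{-6}$ M by factor 2 down to
  $6.25\times10^{-8}$ M, 60 s association, 300 s dissociation;
  `design_eb_weak_binder()` is the shortened 30 s / 60 s variant with a
  sixth dilution ($3.125\times10^{-8}$ M);
* slow sulfonamide binder, `design_slow_binder()`: $2\times10^{-4}$ M by
  factor 2 down to $2.5\times10^{-5}$ M, 240 s association, 480 s
  dissociation (the regime where incomplete dissociation is seen);
* 10 Hz sampling, one blank before and one after the ladder, 25 °C.

Noise is additive, homoscedastic, Gaussian, specified as a percentage of
the series' maximum noise-free amplitude (default 0.5%, chosen as a
realistic instrument noise floor relative to the favourable 2–30% signal
range; the reliability threshold below flags traces under 1%). Amplitudes
follow the equilibrium saturation law $A(c) = A_{max}\, c/(c + K_D)$ by
default, which reproduces the concentration–response correlation a real
series shows while the *fit* still treats every amplitude as free — the
estimator never assumes the law the generator used. An independent
per-trace amplitude option exists, as does a linear baseline drift term.
All randomness flows from explicit integer seeds; per-trace seeds are
derived deterministically from the series seed.

The generator does **not** emulate photobleaching, flow artefacts,
mass-transport limitation, heteroscedastic or correlated noise, nor the
electrically actuated dynamic mode (unsuitable for these analytes). Passing
recovery tests on this generator therefore demonstrates the estimator is
correct *for the stated noise model*, not that real instrument data are
this well behaved.

`simulate_pose_set()` plays the same role for the docking post-analysis: a
seeded mixture of binding "sites" with Gaussian positional scatter,
abundance weights and Gaussian energy magnitudes (kcal/mol, larger =
stronger).

## Global fitting

`fit_global()` estimates $k_a$, $k_d$ (and $f_\mathrm{res}$ under the
incomplete model) *shared across all traces of a series*, with per-trace
$A$ and $y_0$, by bounded Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`). Numerical choices:

* Rates are fitted as $\log k_a$, $\log k_d$ — this enforces positivity
  without active bounds and conditions the problem across the ~6 orders of
  magnitude the package must cover; reported uncertainties are transformed
  back by the delta method. $f_\mathrm{res}$ is box-constrained to
  $[0,1]$.
* Convergence tolerances are `ftol = ptol = 1e-15` (relative cost/step),
  up to 1024 iterations; the residual Jacobian is the optimizer's
  numerically stable forward-difference approximation.
* At least two distinct concentrations are required: one trace determines
  only $k_\mathrm{obs}$, never $k_a$ and $k_d$ separately
  (`identifiability_error`). A warning is raised when
  $\max(k_\mathrm{obs})\cdot(t_d - t_a) < 1$, i.e. the association window
  ends long before the plateau.
* Starting values (`initial_guess()`): per-phase rates come from the
  log-linear regression of first signal differences — for a
  mono-exponential on a uniform grid the differences are exactly
  proportional to $e^{-kt}$, so the estimate is plateau-free and exact on
  noise-free data. Long noisy segments are first averaged into ≤60 equal
  bins (equal bins on a uniform grid keep the binned means exactly
  exponential while suppressing difference noise); if the regression is
  unusable the half-rise time supplies a coarse fallback. $k_a$ then comes
  from the least-squares slope of $k_\mathrm{obs}$ against $c$.
* Two degenerate local minima occur in practice: $k_a c_{max} \ll k_d$
  (the fit has lost all concentration dependence) and
  $k_a c_{min}\,\Delta t \gg 1$ (every transient pushed below the sampling
  resolution). `fit_global()` detects both and retries from seeded
  jittered starts; with an explicit `n_starts > 1` it multi-starts
  unconditionally. Everything is deterministic given data, model and seed.
* Ties in `select_dissociation_model()` (complete vs incomplete, compared
  by small-sample-corrected AIC) favour the simpler complete model.

Uncertainty comes in two flavours, because reported "±" values can mean
either: `estimate_uncertainty(..., "curvature")` gives standard errors from
the local quadratic approximation at the optimum (what a single fit can
know), and `"bootstrap"` resamples residuals within each trace and refits —
both seeded. Replicate experiments are summarized by
`aggregate_replicates()` as the mean ± sample SD per parameter, with
$K_A$, $K_D$ summarized from the *per-replicate* constants rather than the
ratio of means (Jensen's inequality makes these differ whenever replicates
disagree).

## Quality checks

* `percent_change()` flags traces whose peak association-phase change
  (relative to the mean pre-association baseline — robust to single-sample
  noise) is below 1%: below that level fitted parameters carry high
  standard deviations.
* `linearity_check()` fits the ordinary least-squares line through
  (concentration, response) points and reports $R^2$. It is descriptive
  only — a ladder spanning $c \gtrsim K_D$ saturates, so linearity is a
  regime check, not a model claim.
* `kinetic_table()` renders `(value ± SD) × 10^n` entries at 3 significant
  figures (plain style for exponents in $[-2, 2]$), matching the
  conventional layout of kinetic summary tables, with a
  `parse_measure()` inverse for round-tripping.

## Docking-site post-analysis

`cluster_poses()` groups pose centroids by single linkage at a Euclidean
cutoff (default 3.5 Å — hydrogen-bond-contact scale; configurable since
the clustering behind published pose figures is rarely specified):
poses share a site exactly when connected by a chain of pairwise distances
within the cutoff, computed via `hclust(method = "single")` cut at the
cutoff height and verified in the tests against a brute-force
transitive-closure oracle. `rank_sites()` returns the most *common* site
(highest abundance) and the most *strongly bonded* one (highest best
member energy) — the two views used when narrating pose maps — with
documented tie-breaks (abundance ties → higher best energy → lower index).
Groove assignment requires the receptor structure and is out of scope;
clusters live in coordinate space with optional user labels.

## Degenerate inputs and edge cases

Constructors validate eagerly with classed conditions
(`invalid_parameter_error`, `out_of_window_error`, `validation_error`, …),
manifest validation reports *all* problems at once, and the CLI maps
validation failures to exit code 2 and non-convergence to 3. Flat traces
yield a guess failure carrying per-trace diagnostics; constant responses
make `linearity_check()` report $R^2 = 0$ with a degenerate flag; an empty
pose set clusters to an empty list, while ranking and energy fractions on
empty input are errors.

## Problem sizes used by the test suite

The examples and tests run at the full designs where speed permits (the
headline recovery checks use the complete 10 Hz designs, ~18–29 thousand
residual points per fit, well under a second each) and at reduced sampling
rates (1–5 Hz) or shortened ladders for repeated-fit studies such as the
200-replicate confidence-interval coverage simulation and the
oracle-equivalence grid over $k_a \in [10, 10^7]$,
$k_d \in [10^{-3}, 1]$, $f_\mathrm{res} \in \{0, 0.3, 0.7\}$ (each grid
point uses a design scaled to its own relaxation times). These sizes are
the package's own choice of a thorough-but-quick default; nothing in the
methodology depends on them.

## Known limitations

* Only the 1:1 model (plus the residual-fraction extension) is
  implemented: no bivalent, heterogeneous-ligand or mass-transport-limited
  kinetics.
* Rate constants are per-temperature; no Arrhenius/van 't Hoff modelling
  across temperatures.
* The incomplete-dissociation plateau is one defensible parameterisation
  of "the signal does not return to baseline"; slow second-phase decays
  cannot be distinguished from a true plateau within a finite window.
* The noise model is deliberately simple (see above); inverse-variance
  weighting is available but estimates per-trace variances only from the
  baseline window.

## A worked example

```{r example}
truth <- rate_parameters(k_a = 6.98e5, k_d = 0.358, A = 30, y0 = 0)
series <- simulate_series(truth, design_eb_standard(sampling_rate = 2),
                          noise_spec(sigma_pct_fullscale = 0.5, seed = 42))
fit <- fit_global(blank_correct(series))
fit

amp <- data.frame(
  concentration = fit$concentrations,
  response = fit$params$A
)
linearity_check(amp)

kinetic_table(kinetic_row(fit, system = "synthetic intercalator"))
```
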