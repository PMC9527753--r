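# switchkin

Global analysis of small-molecule–DNA binding kinetics from real-time
fluorescence sensorgrams (switchSense-style biosensors), for researchers
who measure association/dissociation cycles of a candidate DNA binder over
a concentration ladder and want rate constants with honest uncertainties —
plus the docking-pose post-analysis that typically accompanies such
studies.

## The model

Each trace is described by the 1:1 interaction model. Association relaxes
with the pseudo-first-order observed rate *k*<sub>obs</sub> = *k*<sub>a</sub>·*c* + *k*<sub>d</sub>:

    F(t) = y0 + A (1 − exp(−(ka·c + kd)(t − ta))),    ta ≤ t < td
    F(t) = y0 + Ad (fres + (1 − fres) exp(−kd (t − td))),    t ≥ td

with per-trace amplitude *A* and baseline *y*<sub>0</sub> (% fluorescence
change), shared rate constants *k*<sub>a</sub> (M⁻¹s⁻¹) and
*k*<sub>d</sub> (s⁻¹), and a residual bound fraction
*f*<sub>res</sub> ∈ [0, 1] for analytes that do not dissociate completely
under buffer flow (*f*<sub>res</sub> = 0 recovers the plain decay). At
equilibrium *K*<sub>A</sub> = *k*<sub>a</sub>/*k*<sub>d</sub> and
*K*<sub>D</sub> = 1/*K*<sub>A</sub>.

`fit_global()` estimates the shared rates over *all* traces of a
concentration series simultaneously (bounded Levenberg–Marquardt on
log-rates, free per-trace amplitude/baseline), `select_dissociation_model()`
chooses between complete and incomplete dissociation by corrected AIC,
`estimate_uncertainty()` offers curvature and bootstrap standard errors,
and `aggregate_replicates()` summarizes replicate experiments as
mean ± SD (constants averaged per replicate, not as ratios of means).
Blank runs feed `blank_correct()`; `percent_change()` flags traces whose
signal change is below the ~1% reliability threshold; `linearity_check()`
reports the concentration–response line; `kinetic_table()` renders
publication-style `(value ± SD) × 10^n` tables. A seeded generator
(`simulate_series()`, `simulate_pose_set()`) reproduces the standard
measurement designs so the whole pipeline is testable without instrument
data, and `cluster_poses()`/`rank_sites()` turn docking pose sets into
binding sites ranked by abundance and by best binding energy.

## Worked example

```r
library(switchkin)

truth  <- rate_parameters(k_a = 6.98e5, k_d = 0.358, A = 30, y0 = 0)
series <- simulate_series(truth, design_eb_standard(),
                          noise_spec(sigma_pct_fullscale = 0.5, seed = 42))
fit <- fit_global(blank_correct(series))
fit
#> Global 1:1 kinetic fit (complete dissociation, uniform weighting)
#>   k_a = 6.892e+05 +/- 3.5e+03 M^-1 s^-1
#>   k_d = 0.3587 +/- 0.00059 s^-1
#>   K_A = 1.921e+06 M^-1, K_D = 5.205e-07 M
#>   RSS = 267.6 over 18255 points, AICc = -7.706e+04
```

The simulated intercalator-like series (five concentrations, 1×10⁻⁶ →
6.25×10⁻⁸ M, 60 s association / 300 s dissociation at 10 Hz, 0.5%
full-scale noise) is recovered to ~1% in *k*<sub>a</sub> and ~0.2% in
*k*<sub>d</sub>; the quoted ± are curvature standard errors of this single
fit. `K_A`/`K_D` are derived from the fitted rates, so their product is
exactly 1.

```r
percent_change(Filter(Negate(is_blank), series)[[1]])
#> Peak fluorescence change: 20.1% (reliable, threshold 1%)

kinetic_table(kinetic_row(fit, system = "synthetic intercalator"))
#>                   system temperature            mode                   k_a             k_d                   K_D                  K_A
#> 1 synthetic intercalator          25 static_standard (6.89 ± 0.035) × 10^5 0.359 ± 0.00059 (5.2 ± 0.028) × 10^-7 (1.92 ± 0.01) × 10^6
```

Docking post-analysis on a synthetic two-site pose set:

```r
ps <- simulate_pose_set(list(
  list(centroid = c(0, 0, 0),  spread = 0.8, weight = 8, energy_mean = 6.9, energy_sd = 0.3),
  list(centroid = c(14, 3, 0), spread = 0.8, weight = 2, energy_mean = 8.0, energy_sd = 0.3)),
  n_poses = 100, seed = 7)
site_report(ps, cutoff = 3.5)$clusters
#>   cluster abundance          x         y           z best_energy representative
#> 1       2        81 -0.0487052 0.1816811 -0.02985289    7.581947       pose_010
#> 2       1        19 14.0377715 2.7446843  0.17503231    8.633839       pose_019
```

The most *common* site (81/100 poses) and the most *strongly bonded* one
(best energy 8.63 kcal/mol) are different clusters here — the two rankings
`rank_sites()` distinguishes.

A command-line wrapper is installed at `exec/switchkin`
(subcommands `simulate`, `fit`, `report`, `sites`; see `run_cli()`).

## Vignette

`vignettes/switchsense-kinetics.Rmd` documents the model and its
assumptions, the generator's scope, the optimizer's numerical choices,
degenerate-input behaviour, and known limitations.
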