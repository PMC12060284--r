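# seepfate

Desk-scale modelling of the fate of methane released from seafloor seeps on
a continental shelf.

Methane bubbles rising from a seep partition among three pathways: a small
fraction reaches the atmosphere directly with the bubble; the rest dissolves
and is then either **ventilated** to the atmosphere by wind-driven air–sea
gas exchange or **biodegraded** to CO₂ and water by methanotrophic bacteria.
Because CO₂ is a much weaker greenhouse gas than methane over decades, this
three-way split controls the climate impact of a seep. `seepfate` is for
biogeochemical modellers and environmental scientists who want to explore
that split as a function of depth, season, wind and biodegradation rate.

The package implements the full chain:

* **Single-bubble model** — Peng–Robinson gas density (with volume
  translation), modified Henry's law solubility, Eötvös/Morton shape
  regimes, clean-bubble rise velocity (Fan–Tsuchiya) and mass transfer
  (Sh = 1.13 Pe^1/2), integrated with adaptive stepping to yield the
  fraction of methane dissolved per metre and the directly surfaced
  fraction.
* **Biodegradation kinetics** — the tracer-experiment generating model
  C(t) = C_tot − (C_tot − C_b)·2^(−t/t½(T)) with Q₁₀ = 2 temperature
  scaling and k₁ = ln 2 / t½; maximum-likelihood estimation and
  affine-invariant ensemble MCMC under uniform priors
  (t½ ∈ [0.25, 100] d).
* **Dissolved transport** — the 1-D diffusion–reaction equation
  ∂C/∂t = ∂/∂z(K ∂C/∂z) − k₁C with a zero-flux bottom boundary and a
  wind-parametrized surface flux j = k_w C₀,
  k_w = a U₁₀² (Sc/660)^(−1/2), a = 6.97e−7 s/m, Sc = 677; solved by a
  finite-volume Crank–Nicolson scheme (second order in space and time,
  mass-conservative to ~11 significant digits).
* **Annual fate analysis** — 36-member ensembles of depletion runs spread
  through the year, half-life sweeps over [1, 1000] d, and the normalized
  ventilation rate v = Ṁ_atm/M, directly comparable with k₁.
* **Synthetic environment** — parametric seasonal eddy-diffusivity fields
  (winter-mixed column, summer pycnocline), AR(1) wind, and simulated
  tritium-tracer datasets, so the whole chain runs without external data.

## Worked example

A 65 m shelf station, a clean 4.5 mm methane bubble, and a 16-day
biodegradation half-life (the upper end of the tracer-experiment range):

```r
library(seepfate)

scen <- make_scenario(65, seed = 1)              # synthetic seasonal station
bub  <- integrate_bubble(65, d0 = 4.5e-3,
                         profile = scen, day = 15)
bub$deposition
#> <deposition_profile> 65 cells to 65 m; dissolved 0.9996, surfaced 0.0004

bal <- run_until_depleted(bub$deposition, scen, t12 = 16, start_day = 15)
round(terminal_fractions(bal), 4)
#>      bubble  ventilated biodegraded
#>      0.0004      0.6460      0.3537

ens <- annual_ensemble(bub$deposition, scen, t12 = 16, n_starts = 36)
round(ens$mean, 4)
#>      bubble  ventilated biodegraded
#>      0.0004      0.3877      0.6119
```

Reading this: the bubble dissolves 99.96% of its methane before surfacing.
A mid-January release ventilates 65% of the methane (winter-mixed column,
fast vertical transport to the surface); averaged over release dates across
the whole year, the summer pycnocline traps dissolved methane at depth and
biodegradation wins — 61% biodegraded at this station, consistent with the
57–68% range reported for a 65 m seep when t½ is 9–16 days.

Fitting the kinetics to a simulated tracer experiment:

```r
d <- simulate_tracer_experiment(tracer_design(), seed = 1)
sample_posterior(d, seed = 1)
#> <kinetics_posterior> affine-invariant ensemble MCMC
#>   parameter     mle stderr     p16     p50      p84
#> 1   t12_ref 16.9500 4.8597 13.6771 18.9316 26.97526
#> 2        Cb  0.7180 0.2988  0.4730  0.7990  1.15246
#> 3      Ctot  4.5778 0.4221  4.1572  4.6197  5.08164
#> 4  ln_sigma -0.2996 0.1543 -0.3589 -0.1949 -0.02052
#> acceptance fraction 0.58; min ESS 1477
```

`run_pipeline(pipeline_config(station_depth = 65))` chains all stages and
writes CSV outputs plus a provenance record;
`inst/scripts/seepfate-cli.R` exposes the same stages as shell subcommands
(`simulate-env`, `fit-kinetics`, `run-bubble`, `run-fate`, `sweep`,
`run-all`).

## Layout

* `R/` — environment generator, kinetics (MLE + MCMC), bubble model,
  transport wrappers, fate ensembles, pipeline orchestration
* `src/` — Crank–Nicolson finite-volume kernel (Rcpp)
* `vignettes/methane-fate-methods.Rmd` — model description, assumptions,
  numerical choices and limitations
* `tests/testthat/` — unit, property and acceptance suites
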