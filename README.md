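# metacrate

Analysis of two-diet crossover metabolism-crate trials in ruminants, built
around the question of whether a forage swap (e.g. plantain, *Plantago
lanceolata*, in place of perennial ryegrass) dilutes urinary nitrogen and so
reduces nitrate leaching from grazed pastures. The package covers the whole
chain such a trial needs:

- **Intake bookkeeping** — daily dry matter intake (DMI) from offered and
  refused fresh herbage, feed water from the diet's DM%, apparent
  digestibility.
- **Liquid-phase digesta kinetics** — fecal cobalt (CoEDTA marker) curves,
  converted to a fecal-water basis and fitted to a one-compartment model
  with delay, `C(t) = c0·exp(−k(t−τ))` for `t ≥ τ` (an age-dependent
  gamma-2 family is also available). Derived parameters: gastrointestinal
  liquid fill `GIF = dose/c0` (marker dilution), rumen retention time
  `RRT = 1/k`, intestinal transit time `ITT = τ`, mean retention time
  `GMRT = RRT + ITT`, and fractional outflow rate `FOR = 100·k` %/h.
- **Water and nitrogen budgets** — per animal-phase mass balances
  (intake = excretion + balance; N intake = fecal N + urinary N +
  retention), with crude protein converted to N at the standard factor 6.25.
- **Crossover inference** — the classical 2×2 crossover diet contrast on
  animal-phase means (equivalent to OLS with diet, phase and animal
  indicators on balanced data), mechanism regressions such as
  `urine output = a_diet + b·(water intake)` with BIC model selection
  (`BIC = n·ln(RSS/n) + p·ln(n)`), and Pearson correlations.
- **Environmental translation** — a urinary-N concentration reduction
  mapped to urine-patch N loading (`baseline·(1 − reduction)`) and to a
  relative nitrate-leaching change under a one-parameter power law
  calibrated so a 64.5 % loading reduction gives a 56.1 % leaching
  reduction.
- **A synthetic-trial generator** — `generate_trial()` draws complete,
  validated crossover datasets (8 animals, both sequences, 3 measurement
  days per phase, marker curves at 0–72 h post-dose) from configurable
  structural truths, so every analysis stage can be checked by parameter
  recovery.

## Worked example

```r
library(metacrate)

ds  <- generate_trial(generator_config(seed = 42))  # synthetic 8-deer trial
res <- analyze_trial(ds)                            # full pipeline
res
```

```
Crossover trial analysis (PL vs RG), 16 animal-phases
Key diet contrasts (treatment vs control):
  dmi               1.581 vs    1.449 (P = 0.0106)
  urine_n_conc      2.682 vs    9.432 (P = 0.000273)
  water_urine       8.743 vs    4.854 (P = 4.17e-05)
  n_intake         40.145 vs   52.828 (P = 0.000222)
  urine_n          22.463 vs   42.449 (P = 0.00646)
  gif               7.069 vs    3.022 (P = 0.0018)
Urine output model: water + diet + water_diet (BIC 8.05)
r(urine output, urinary N conc) = -0.865
Urine-patch loading 400 -> 114 kg N/ha (71.6% conc. reduction); leaching -63.2%
```

Read: on the plantain diet the simulated deer eat slightly more dry matter
(1.58 vs 1.45 kg DM/d) but ingest far more water, so urine output nearly
doubles (8.7 vs 4.9 L/d) and urinary N is diluted (2.7 vs 9.4 g N/L)
while daily urinary N falls (22 vs 42 g/d, driven by the lower N intake).
The diluted urine translates to a urine-patch loading of 114 instead of
400 kg N/ha and, under the calibrated power law, a 63 % smaller nitrate
leaching loss.

Single marker curves can be fitted directly:

```r
fit <- fit_curve(ds$marker_series[[1]])
derive_params(fit, co_dose_mass(ds$doses[[1]]))
```

```
Liquid-phase kinetics: FOR 8.66 %/h | GIF 7.06 L | RRT 11.55 h | ITT 8.00 h | GMRT 19.55 h
```

A command-line wrapper (`simulate` / `analyze` subcommands) is installed at
`system.file("scripts", "metacrate.R", package = "metacrate")`; it reads and
writes the documented CSV quartet (`records.csv`, `compositions.csv`,
`doses.csv`, `marker.csv`) and emits `budgets.csv`, `kinetics.csv`,
`effects.csv`, `regressions.json` and `environment.json`.

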