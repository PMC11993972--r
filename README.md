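# medflysit

Individual-based simulation of sterile-male release programs in the
Mediterranean fruit fly (*Ceratitis capitata*).

The medfly is a globally distributed, highly polyphagous agricultural pest,
and the classic target of the sterile insect technique (SIT): mass releases
of sterilised males that soak up wild females' matings and crash offspring
production. Newer genetic designs change the economics of a release program -
CRISPR *transformer*-knockout sex conversion turns part of the XX brood into
fertile phenotypic males (more released males per kilogram of diet), and
pgSIT-style genetic sterilisation avoids the mating-competitiveness cost of
irradiation. `medflysit` is for quantitative ecologists and genetic-biocontrol
modellers who want to compare such release systems head to head in a common
demographic model: how fast does each crush the female population, at what
release ratio, and how robust is suppression to batching releases?

## The model

Weekly time steps, overlapping generations, panmixia. Each week:
releases → mating → reproduction → larval competition → mortality & aging.

* **Demography.** Larva 1 wk, pupa 2 wk, adult thereafter. Age-based
  conditional survival is 1 up to age 4, then declines linearly in cohort
  numbers to 0 at age 13 (females) / 19 (males); adults additionally survive
  background hazards at 0.9/wk.
* **Mating.** Males are sampled per mating with probability ∝ count ×
  fitness (0.83 irradiated, 1.0 otherwise). Females mate on emergence and
  remate with probability 1/3 per week under first-male sperm precedence:
  first mate fertile ⇒ fertility 1 (absorbing); first mate sterile ⇒ 0,
  "rescued" to a 50% weekly clutch probability by a later fertile mate.
* **Reproduction.** Each fertile mated female past her first adult week lays
  a Poisson(9.37) clutch; sexes 1:1.
* **Density dependence.** A weekly egg cohort of size *n* survives at the
  Beverton–Holt rate
  *s(f) = s₁ · β / ((β − 1) f + 1)*, with *f = n / n₀*, β = 10 and
  *s₁* = 0.3344/9.373; survivors are binomial. The scale *n₀*
  (`expected_larvae`) is auto-calibrated so a no-release population holds
  50,000 adult females through a 50-week burn-in.
* **Releases.** Effort is a *release ratio*: weekly sterile males as a
  fraction of equilibrium wild adult males. Equal rearing food gives a
  sex-conversion strain `survival × (1 + xx_male_fraction)` effective males
  per unit effort - 1.0 (standard SIT), 1.011 (DmPub.2-based), 1.1475
  (CcPub.1-based, ≈15% above standard). Releases every *k* weeks are *k*
  times larger, so total effort is interval-invariant. Runs stop at
  elimination (zero wild individuals at all stages) or after 100 release
  weeks.

See `vignette("medfly-sit-model")` for the full account, including the
calibration algebra and known limitations.

## Worked example

```r
library(medflysit)

cfg <- fixture_scenario("desk")            # 0.1x scale: 5,000 adult females
cal <- calibrate_equilibrium(cfg, pilot = FALSE)
cal$f_star                                  # 0.5965 - equilibrium crowding
round(cal$expected_larvae)                  # 622131 larvae at f = 1 (unscaled)

cfg$expected_larvae <- cal$expected_larvae
sim <- run_simulation(cfg, strain_profiles("CcPub1_pgSIT"),
                      release_schedule(release_ratio = 1), seed = 1)
sim
#> <medfly_sim> CcPub1_pgSIT, ratio 1 every 1 wk, seed 1
#>   equilibrium wild males: 6,263
#>   population eliminated 55 week(s) after first release
```

The run equilibrates 5,000 females for 50 weeks (the measured wild-male
equilibrium, 6,263, exceeds the female count because males live longer), then
releases 1 × 6,263 × 1.1475 ≈ 7,187 sterile CcPub.1-pgSIT males weekly; the
wild population (all stages) hits zero 55 weeks after the first release.
`tidy(sim)` returns the week-by-week trajectory, `glance(sim)` a one-row
summary, `autoplot(sim)` the female trajectory plot. Factorial designs run
through `experiment_grid()` + `run_grid()` + `summarize_grid()`, and
`inst/cli/medflysit.R` wraps calibrate/run/grid/fixtures for shell use with a
YAML config (`load_config()`).

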