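# Shared fixtures: tiny configurations and hand-built populations.

# micro-scale config with short phases for fast unit tests
tiny_config <- function(...) {
  fixture_scenario("micro", burn_in_weeks = 10, horizon_weeks = 10, ...)
}

# a calibrated config (analytic calibration only, deterministic)
calibrated <- function(cfg) {
  cfg$expected_larvae <- calibrate_equilibrium(cfg, pilot = FALSE)$expected_larvae
  cfg
}

# adult females in a given mating state, past their first adult week unless
# stated otherwise
adult_females <- function(n, mating = "first_fertile", weeks_adult = 2L,
                          cfg = sim_config()) {
  population("wild", "female", age = medflysit:::adult_age(cfg) + weeks_adult,
             mating = mating, weeks_adult = weeks_adult, n = n)
}

adult_males <- function(n, origin = "wild", fitness = 1, strain = NA_character_,
                        cfg = sim_config()) {
  population(origin, "male", age = medflysit:::adult_age(cfg) + 1L,
             weeks_adult = 1L, fitness = fitness, strain = strain, n = n)
}
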