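# Simulation configuration: demographic rates, mating parameters,
# density-dependence, calibration and run control.

#' Default male age-based survival schedule
#'
#' Conditional weekly survival probabilities indexed by age in weeks (0-18).
#' The first five entries are 1 (juvenile stages carry no age-based mortality;
#' all juvenile mortality is expressed at the larval-competition step), after
#' which survival declines so that the number of survivors in a cohort falls
#' linearly, reaching zero at week 19.
#'
#' @return Numeric vector of length 19.
#' @export
default_male_survival <- function() {
  c(1, 1, 1, 1, 1, 13 / 14, 12 / 13, 11 / 12, 10 / 11, 9 / 10, 8 / 9, 7 / 8,
    6 / 7, 5 / 6, 4 / 5, 3 / 4, 2 / 3, 1 / 2, 0)
}

#' Default female age-based survival schedule
#'
#' As [default_male_survival()], but reaching zero at week 13: females do not
#' survive beyond their thirteenth week.
#'
#' @return Numeric vector of length 13.
#' @export
default_female_survival <- function() {
  c(1, 1, 1, 1, 1, 7 / 8, 6 / 7, 5 / 6, 4 / 5, 3 / 4, 2 / 3, 1 / 2, 0)
}

#' Build a simulation configuration
#'
#' Collects every demographic, mating, density-dependence, calibration and
#' run-control parameter of the weekly-time-step medfly model. Defaults are
#' the published parameterisation: low-density growth rate beta = 10, larval
#' survival at carrying-capacity density 0.3344/9.373, mean weekly clutch of
#' 9.37 eggs, weekly remating probability 1/3, 50% fertility after a
#' sterile-then-fertile mating sequence, weekly adult background survival 0.9,
#' and an initial population of 50,000 adult females equilibrated for 50 weeks
#' before releases.
#'
#' @param beta Low-density growth rate of the Beverton-Holt larval survival
#'   term (dimensionless, >= 1).
#' @param base_larval_survival Larval survival probability at
#'   carrying-capacity density (competition factor f = 1).
#' @param poisson_mean_eggs Mean weekly clutch size (eggs per reproducing
#'   female per week).
#' @param remating_prob Weekly probability that an already-mated female
#'   remates.
#' @param rescue_fertility Weekly clutch probability for a female whose first
#'   mate was sterile and who later remated with a fertile male.
#' @param adult_background_survival Weekly adult survival from causes other
#'   than age (applies on top of the age schedules).
#' @param male_age_survival,female_age_survival Conditional weekly survival
#'   schedules indexed by age 0..18 (males) and 0..12 (females); the first
#'   five entries must be 1 and the last entry 0.
#' @param larval_duration,pupal_duration Stage durations in weeks; adults
#'   emerge at age `larval_duration + pupal_duration`.
#' @param init_adult_females Adult female count the no-release population is
#'   calibrated to (before scaling).
#' @param scale_factor Linear population scaling for desk-scale runs; scales
#'   `init_adult_females`, `expected_larvae` and absolute release counts, and
#'   leaves all per-capita rates unchanged.
#' @param burn_in_weeks Weeks of no-release equilibration before releases.
#' @param horizon_weeks Weeks of release phase (runs stop earlier on
#'   elimination).
#' @param expected_larvae Weekly larval count at which the competition factor
#'   f equals 1, in unscaled (scale_factor = 1) units. `NULL` (the default)
#'   requests automatic calibration so the no-release equilibrium adult female
#'   count equals `init_adult_females` (see [calibrate_equilibrium()]).
#' @param seed Default RNG seed used when a run does not pass one explicitly.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [fixture_scenario()], [calibrate_equilibrium()], [run_simulation()]
#' @examples
#' cfg <- sim_config(scale_factor = 0.01)
#' cfg$beta
#' @export
sim_config <- function(beta = 10,
                       base_larval_survival = 0.3344 / 9.373,
                       poisson_mean_eggs = 9.37,
                       remating_prob = 1 / 3,
                       rescue_fertility = 0.5,
                       adult_background_survival = 0.9,
                       male_age_survival = default_male_survival(),
                       female_age_survival = default_female_survival(),
                       larval_duration = 1,
                       pupal_duration = 2,
                       init_adult_females = 50000,
                       scale_factor = 1,
                       burn_in_weeks = 50,
                       horizon_weeks = 100,
                       expected_larvae = NULL,
                       seed = 1L) {
  cfg <- structure(
    list(
      beta = beta,
      base_larval_survival = base_larval_survival,
      poisson_mean_eggs = poisson_mean_eggs,
      remating_prob = remating_prob,
      rescue_fertility = rescue_fertility,
      adult_background_survival = adult_background_survival,
      male_age_survival = male_age_survival,
      female_age_survival = female_age_survival,
      larval_duration = as.integer(larval_duration),
      pupal_duration = as.integer(pupal_duration),
      init_adult_females = init_adult_females,
      scale_factor = scale_factor,
      burn_in_weeks = as.integer(burn_in_weeks),
      horizon_weeks = as.integer(horizon_weeks),
      expected_larvae = expected_larvae,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
  validate_sim_config(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  beta %.3g; base larval survival %.6f; mean eggs %.3g/week\n",
              x$beta, x$base_larval_survival, x$poisson_mean_eggs))
  cat(sprintf("  remating %.3g/week; rescue fertility %.3g; background adult survival %.3g\n",
              x$remating_prob, x$rescue_fertility, x$adult_background_survival))
  cat(sprintf("  stages: larva %d wk, pupa %d wk (adults from age %d)\n",
              x$larval_duration, x$pupal_duration, adult_age(x)))
  cat(sprintf("  init adult females %s x scale %.4g; burn-in %d wk; horizon %d wk\n",
              format(x$init_adult_females, big.mark = ","), x$scale_factor,
              x$burn_in_weeks, x$horizon_weeks))
  cat(sprintf("  expected_larvae: %s\n",
              if (is.null(x$expected_larvae)) "auto-calibrated" else
                format(round(x$expected_larvae), big.mark = ",")))
  invisible(x)
}

config_error <- function(key, msg) {
  stop(sprintf("invalid configuration: `%s` %s", key, msg), call. = FALSE)
}

check_prob <- function(value, key) {
  if (!is.numeric(value) || length(value) != 1 || is.na(value) ||
      value < 0 || value > 1) {
    config_error(key, "must be a single probability in [0, 1]")
  }
}

check_schedule <- function(sched, key) {
  if (!is.numeric(sched) || anyNA(sched) || any(sched < 0) || any(sched > 1)) {
    config_error(key, "must be probabilities in [0, 1]")
  }
  if (length(sched) < 6) {
    config_error(key, "must cover at least ages 0-5")
  }
  if (any(sched[1:5] != 1)) {
    config_error(key, "must equal 1 for ages 0-4 (juvenile mortality is expressed only at larval competition)")
  }
  if (sched[length(sched)] != 0) {
    config_error(key, "must end in 0 (no survival past the final age)")
  }
}

validate_sim_config <- function(cfg) {
  if (!is.numeric(cfg$beta) || length(cfg$beta) != 1 || cfg$beta < 1) {
    config_error("beta", "must be a single number >= 1")
  }
  check_prob(cfg$base_larval_survival, "base_larval_survival")
  if (!is.numeric(cfg$poisson_mean_eggs) || cfg$poisson_mean_eggs <= 0) {
    config_error("poisson_mean_eggs", "must be positive")
  }
  check_prob(cfg$remating_prob, "remating_prob")
  check_prob(cfg$rescue_fertility, "rescue_fertility")
  check_prob(cfg$adult_background_survival, "adult_background_survival")
  check_schedule(cfg$male_age_survival, "male_age_survival")
  check_schedule(cfg$female_age_survival, "female_age_survival")
  if (cfg$larval_duration < 1) config_error("larval_duration", "must be >= 1")
  if (cfg$pupal_duration < 1) config_error("pupal_duration", "must be >= 1")
  if (!is.numeric(cfg$init_adult_females) || cfg$init_adult_females <= 0) {
    config_error("init_adult_females", "must be positive")
  }
  if (!is.numeric(cfg$scale_factor) || cfg$scale_factor <= 0) {
    config_error("scale_factor", "must be positive")
  }
  if (cfg$burn_in_weeks < 1) config_error("burn_in_weeks", "must be >= 1")
  if (cfg$horizon_weeks < 1) config_error("horizon_weeks", "must be >= 1")
  if (!is.null(cfg$expected_larvae) &&
      (!is.numeric(cfg$expected_larvae) || cfg$expected_larvae <= 0)) {
    config_error("expected_larvae", "must be positive (or NULL for auto-calibration)")
  }
  cfg
}

# age (weeks since egg) at which adults emerge
adult_age <- function(cfg) cfg$larval_duration + cfg$pupal_duration

#' Named scaled-down fixture scenarios
#'
#' Deterministic, documented scenarios used throughout the test-suite and in
#' examples. All share the published rates and differ only in
#' `scale_factor`:
#' \describe{
#'   \item{"micro"}{scale 0.002 (~100 adult females) - fast unit tests.}
#'   \item{"desk"}{scale 0.1 (5,000 adult females) - desk-scale experiments.}
#'   \item{"paper"}{scale 1 (50,000 adult females) - full published scale.}
#' }
#'
#' @param name One of `"micro"`, `"desk"`, `"paper"`.
#' @param ... Further arguments passed to [sim_config()] to override defaults.
#' @return A `sim_config`.
#' @examples
#' fixture_scenario("desk")$init_adult_females * fixture_scenario("desk")$scale_factor
#' @export
fixture_scenario <- function(name = c("micro", "desk", "paper"), ...) {
  name <- match.arg(name)
  scale <- switch(name, micro = 0.002, desk = 0.1, paper = 1)
  sim_config(scale_factor = scale, ...)
}
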