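# Simulation driver: calibration, burn-in, release phase, elimination
# detection and trajectory metrics.

#' Calibrate the density-dependence scale to a stationary population
#'
#' Finds the `expected_larvae` value (larval count at competition factor
#' f = 1) at which the no-release population is stationary at
#' `init_adult_females` adult females. The value is first computed
#' analytically from the stable age distribution implied by the survival
#' schedules (see [stable_age_structure()]); optionally a stochastic pilot
#' burn-in verifies it and applies a multiplicative correction if the realised
#' equilibrium drifts more than 2%. Because equilibrium size is linear in
#' `expected_larvae` at fixed rates, one correction step suffices.
#'
#' @param config A [sim_config()].
#' @param pilot Run a stochastic pilot burn-in to verify/refine the analytic
#'   value and to measure the equilibrium wild male count empirically?
#' @param seed RNG seed for the pilot (defaults to `config$seed`).
#' @return A list: `expected_larvae` (unscaled), `equilibrium_wild_males`
#'   (scaled by `scale_factor`; analytic if `pilot = FALSE`, otherwise the
#'   mean over the last 10 burn-in weeks), `f_star` (equilibrium competition
#'   factor), and `pilot_mean_females` (if piloted).
#' @examples
#' calibrate_equilibrium(fixture_scenario("micro"), pilot = FALSE)$f_star
#' @export
calibrate_equilibrium <- function(config, pilot = TRUE, seed = config$seed) {
  eq <- stable_age_structure(config)
  out <- list(expected_larvae = eq$expected_larvae,
              equilibrium_wild_males = eq$adult_males * config$scale_factor,
              f_star = eq$f_star,
              pilot_mean_females = NA_real_)
  if (!pilot) return(out)

  run_pilot <- function(expected) {
    cfg <- config
    cfg$expected_larvae <- expected
    set.seed(seed)
    pop <- stable_age_population(cfg)
    recs <- vector("list", cfg$burn_in_weeks)
    for (w in seq_len(cfg$burn_in_weeks)) {
      step <- sim_week(pop, cfg)
      pop <- step$pop
      recs[[w]] <- step$record
    }
    dplyr::bind_rows(recs)
  }

  target <- config$init_adult_females * config$scale_factor
  traj <- run_pilot(out$expected_larvae)
  tail20 <- utils::tail(traj, 20L)
  mean_f <- mean(tail20$wild_females)
  if (abs(mean_f - target) / target > 0.02) {
    # equilibrium size is linear in expected_larvae; rescale and re-verify
    out$expected_larvae <- out$expected_larvae * target / mean_f
    traj <- run_pilot(out$expected_larvae)
    tail20 <- utils::tail(traj, 20L)
    mean_f <- mean(tail20$wild_females)
  }
  if (abs(mean_f - target) / target > 0.25) {
    stop("calibration error: pilot burn-in settled at ", round(mean_f),
         " adult females against a target of ", round(target),
         "; check schedules and scale_factor", call. = FALSE)
  }
  out$pilot_mean_females <- mean_f
  out$equilibrium_wild_males <- mean(utils::tail(traj$wild_males, 10L))
  out
}

#' Run one burn-in + release simulation
#'
#' Executes the weekly life cycle for `burn_in_weeks` weeks with no releases,
#' measures the equilibrium wild adult male count as the mean over the last 10
#' burn-in weeks, then runs the release phase for `horizon_weeks` weeks (or
#' until elimination), injecting sterile-male cohorts per the schedule. A
#' single seeded RNG stream drives the whole run, so identical seed + config
#' reproduce the trajectory bit for bit.
#'
#' @param config A [sim_config()]. If `config$expected_larvae` is `NULL` it is
#'   calibrated analytically (deterministically) first.
#' @param profile A [strain_profile()] (default standard SIT).
#' @param schedule A [release_schedule()] (default ratio 1, weekly).
#' @param seed RNG seed (defaults to `config$seed`).
#' @return An object of class `medfly_sim`: a list with `trajectory` (one row
#'   per simulated week: `phase`, `week`, counts), `config`, `profile`,
#'   `schedule`, `seed`, `equilibrium_wild_males`, `expected_larvae`,
#'   `eliminated`, `elimination_week` (release-phase week, `NA` if censored).
#' @examples
#' sim <- run_simulation(fixture_scenario("micro", burn_in_weeks = 10,
#'                                        horizon_weeks = 5), seed = 1)
#' glance(sim)
#' @export
run_simulation <- function(config, profile = strain_profiles("standard_SIT"),
                           schedule = release_schedule(1), seed = config$seed) {
  stopifnot(inherits(config, "sim_config"),
            inherits(profile, "strain_profile"),
            inherits(schedule, "release_schedule"))
  if (is.null(config$expected_larvae)) {
    config$expected_larvae <- stable_age_structure(config)$expected_larvae
  }
  set.seed(seed)
  pop <- stable_age_population(config)

  records <- vector("list", config$burn_in_weeks + config$horizon_weeks)
  for (w in seq_len(config$burn_in_weeks)) {
    step <- sim_week(pop, config)
    pop <- step$pop
    records[[w]] <- dplyr::bind_cols(
      tibble::tibble(phase = "burn_in", week = w), step$record
    )
  }
  burn <- dplyr::bind_rows(records[seq_len(config$burn_in_weeks)])
  m_eq <- mean(utils::tail(burn$wild_males, 10L))

  eliminated <- FALSE
  elim_week <- NA_integer_
  for (w in seq_len(config$horizon_weeks)) {
    n_rel <- weekly_release_count(schedule, w, m_eq, profile)
    rel <- if (n_rel > 0) make_release_cohort(n_rel, profile, config) else NULL
    step <- sim_week(pop, config, releases = rel)
    pop <- step$pop
    records[[config$burn_in_weeks + w]] <- dplyr::bind_cols(
      tibble::tibble(phase = "release", week = w), step$record
    )
    if (step$record$wild_total == 0) {
      eliminated <- TRUE
      elim_week <- w
      break
    }
  }

  structure(
    list(
      trajectory = dplyr::bind_rows(purrr::compact(records)),
      config = config, profile = profile, schedule = schedule,
      seed = as.integer(seed),
      equilibrium_wild_males = m_eq,
      expected_larvae = config$expected_larvae,
      eliminated = eliminated,
      elimination_week = elim_week,
      final_population = pop
    ),
    class = "medfly_sim"
  )
}

#' @export
print.medfly_sim <- function(x, ...) {
  cat(sprintf("<medfly_sim> %s, ratio %.3g every %d wk, seed %d\n",
              x$profile$name, x$schedule$release_ratio,
              x$schedule$interval_weeks, x$seed))
  cat(sprintf("  equilibrium wild males: %s\n",
              format(round(x$equilibrium_wild_males), big.mark = ",")))
  if (x$eliminated) {
    cat(sprintf("  population eliminated %d week(s) after first release\n",
                x$elimination_week))
  } else {
    cat(sprintf("  not eliminated within %d release weeks (censored); mean females last 20 wk: %.1f\n",
                x$config$horizon_weeks, mean_females_last20(x)))
  }
  invisible(x)
}

#' Weeks from first release to population elimination
#'
#' The first release-phase week in which the wild population (all stages) is
#' zero. Runs that reach the horizon without elimination are censored at the
#' horizon.
#'
#' @param sim A `medfly_sim`.
#' @return Integer weeks; censored runs return the horizon with attribute
#'   `censored = TRUE`.
#' @export
time_to_elimination <- function(sim) {
  stopifnot(inherits(sim, "medfly_sim"))
  if (sim$eliminated) {
    structure(sim$elimination_week, censored = FALSE)
  } else {
    structure(sim$config$horizon_weeks, censored = TRUE)
  }
}

#' Mean adult wild females over the last 20 release weeks
#'
#' Arithmetic mean of the adult wild female count over release-phase weeks
#' `horizon - 19` to `horizon`. Runs eliminated earlier contribute zeros for
#' the missing weeks.
#'
#' @param sim A `medfly_sim`.
#' @return A single number.
#' @export
mean_females_last20 <- function(sim) {
  stopifnot(inherits(sim, "medfly_sim"))
  horizon <- sim$config$horizon_weeks
  weeks <- (horizon - 19L):horizon
  rel <- sim$trajectory[sim$trajectory$phase == "release", ]
  counts <- vapply(weeks, function(w) {
    hit <- rel$week == w
    if (any(hit)) rel$wild_females[hit][1] else 0
  }, numeric(1))
  mean(counts)
}

#' Tidy the weekly trajectory of a simulation
#'
#' @param x A `medfly_sim`.
#' @param ... Unused.
#' @return The trajectory tibble (one row per simulated week).
#' @export
tidy.medfly_sim <- function(x, ...) x$trajectory

#' One-row summary of a simulation
#'
#' @param x A `medfly_sim`.
#' @param ... Unused.
#' @return A one-row tibble: system, ratio, interval, seed, equilibrium wild
#'   males, elimination status/week, censoring, and the mean adult female
#'   count over the last 20 release weeks.
#' @export
glance.medfly_sim <- function(x, ...) {
  tte <- time_to_elimination(x)
  tibble::tibble(
    system = x$profile$name,
    release_ratio = x$schedule$release_ratio,
    interval_weeks = x$schedule$interval_weeks,
    seed = x$seed,
    equilibrium_wild_males = x$equilibrium_wild_males,
    eliminated = x$eliminated,
    elimination_week = as.integer(tte),
    censored = attr(tte, "censored"),
    mean_females_last20 = mean_females_last20(x)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
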