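# Release systems: strain profiles, effective release sizes under equal
# rearing effort, and scheduled sterile-male cohorts.

#' Effective release-size multiplier under equal rearing effort
#'
#' Rearing a strain on the same amount of food as standard SIT yields
#' `rearing_survival_rel` times the juveniles, of which the usual half are XY
#' males and a fraction `xx_male_fraction` of the XX half are fully
#' sex-converted fertile-phenotype males (the rest of the XX half are sterile
#' intersexes that are not released as males). Relative to the standard-SIT
#' baseline of half the reared individuals,
#' `multiplier = rearing_survival_rel * (1 + xx_male_fraction)`.
#'
#' @param rearing_survival_rel Juvenile survival relative to wild type under
#'   equal food, in `[0, 1]`.
#' @param xx_male_fraction Fraction of XX individuals developing as males, in
#'   `[0, 1]`.
#' @return Effective males released per unit standard-SIT effort.
#' @examples
#' effective_release_multiplier(1, 0)        # standard SIT baseline
#' effective_release_multiplier(0.85, 0.35)  # 1.1475, ~15% higher
#' @export
effective_release_multiplier <- function(rearing_survival_rel, xx_male_fraction) {
  for (v in list(rearing_survival_rel = rearing_survival_rel,
                 xx_male_fraction = xx_male_fraction)) {
    if (!is.numeric(v) || anyNA(v) || any(v < 0) || any(v > 1)) {
      stop("`rearing_survival_rel` and `xx_male_fraction` must lie in [0, 1]",
           call. = FALSE)
    }
  }
  rearing_survival_rel * (1 + xx_male_fraction)
}

#' Define a release-system strain profile
#'
#' @param name Identifier.
#' @param sterilisation `"radiation"` or `"genetic"` (pgSIT-style).
#' @param male_mating_fitness Relative mating weight of released males;
#'   defaults to 0.83 for radiation (irradiation mating cost) and 1 for
#'   genetic sterilisation.
#' @param rearing_survival_rel Juvenile survival relative to wild type under
#'   equal food.
#' @param xx_male_fraction Fraction of XX individuals developing as fertile
#'   phenotypic males.
#' @param release_multiplier Effective males per unit standard-SIT effort;
#'   computed with [effective_release_multiplier()] unless stated explicitly.
#' @return An object of class `strain_profile`.
#' @examples
#' strain_profile("custom", "genetic", rearing_survival_rel = 0.9,
#'                xx_male_fraction = 0.2)
#' @export
strain_profile <- function(name, sterilisation = c("radiation", "genetic"),
                           male_mating_fitness = NULL,
                           rearing_survival_rel = 1,
                           xx_male_fraction = 0,
                           release_multiplier = NULL) {
  sterilisation <- match.arg(sterilisation)
  if (is.null(male_mating_fitness)) {
    male_mating_fitness <- if (sterilisation == "radiation") 0.83 else 1
  }
  if (male_mating_fitness <= 0 || male_mating_fitness > 1) {
    stop("`male_mating_fitness` must be in (0, 1]", call. = FALSE)
  }
  if (is.null(release_multiplier)) {
    release_multiplier <-
      effective_release_multiplier(rearing_survival_rel, xx_male_fraction)
  }
  if (release_multiplier < rearing_survival_rel) {
    stop("`release_multiplier` cannot fall below `rearing_survival_rel`",
         call. = FALSE)
  }
  structure(
    list(name = name, sterilisation = sterilisation,
         male_mating_fitness = male_mating_fitness,
         rearing_survival_rel = rearing_survival_rel,
         xx_male_fraction = xx_male_fraction,
         release_multiplier = release_multiplier),
    class = "strain_profile"
  )
}

#' @export
print.strain_profile <- function(x, ...) {
  cat(sprintf("<strain_profile> %s (%s): fitness %.3g, rearing survival %.3g, XX->male %.3g, release multiplier %.6g\n",
              x$name, x$sterilisation, x$male_mating_fitness,
              x$rearing_survival_rel, x$xx_male_fraction,
              x$release_multiplier))
  invisible(x)
}

#' Built-in release systems
#'
#' The five systems compared in the release experiments:
#' \describe{
#'   \item{standard_SIT}{radiation-sterilised wild-type males (baseline).}
#'   \item{DmPub2_radiation / DmPub2_pgSIT}{sex-conversion strain with
#'     wild-type rearing survival and a small fertile XX-male output (stated
#'     effective release size 1.1% above standard), sterilised by radiation or
#'     genetically.}
#'   \item{CcPub1_radiation / CcPub1_pgSIT}{sex-conversion strain with 85%
#'     relative rearing survival and 35% XX-to-male conversion (effective
#'     release size 1.1475, ~15% above standard).}
#' }
#' Radiation profiles carry male mating fitness 0.83; genetic (pgSIT)
#' profiles carry fitness 1.
#'
#' @param name Optional single profile name; if omitted, a named list of all
#'   five profiles is returned.
#' @return A `strain_profile` or a named list of them.
#' @examples
#' strain_profiles("CcPub1_pgSIT")$release_multiplier
#' names(strain_profiles())
#' @export
strain_profiles <- function(name = NULL) {
  # DmPub2's xx_male_fraction is back-solved from its stated 1.1% effective
  # release-size gain (survival 1 => fraction 0.011).
  all <- list(
    standard_SIT = strain_profile("standard_SIT", "radiation"),
    DmPub2_radiation = strain_profile("DmPub2_radiation", "radiation",
                                      xx_male_fraction = 0.011),
    DmPub2_pgSIT = strain_profile("DmPub2_pgSIT", "genetic",
                                  xx_male_fraction = 0.011),
    CcPub1_radiation = strain_profile("CcPub1_radiation", "radiation",
                                      rearing_survival_rel = 0.85,
                                      xx_male_fraction = 0.35),
    CcPub1_pgSIT = strain_profile("CcPub1_pgSIT", "genetic",
                                  rearing_survival_rel = 0.85,
                                  xx_male_fraction = 0.35)
  )
  if (is.null(name)) return(all)
  if (!name %in% names(all)) {
    stop("unknown strain profile `", name, "`; available: ",
         paste(names(all), collapse = ", "), call. = FALSE)
  }
  all[[name]]
}

#' Define a release schedule
#'
#' Release effort is expressed per week as a fraction (`release_ratio`) of
#' the equilibrium wild adult male count. With `interval_weeks > 1`, releases
#' happen every `interval_weeks` weeks at `interval_weeks` times the weekly
#' count, so the total release effort over any horizon is interval-invariant
#' (up to rounding).
#'
#' @param release_ratio Weekly release effort as a fraction of equilibrium
#'   wild adult males (>= 0).
#' @param interval_weeks Weeks between releases (>= 1).
#' @param start_week First release-phase week with a release (>= 1).
#' @return An object of class `release_schedule`.
#' @examples
#' release_schedule(1, interval_weeks = 4)
#' @export
release_schedule <- function(release_ratio = 1, interval_weeks = 1L,
                             start_week = 1L) {
  if (!is.numeric(release_ratio) || release_ratio < 0) {
    stop("`release_ratio` must be >= 0", call. = FALSE)
  }
  if (interval_weeks < 1) stop("`interval_weeks` must be >= 1", call. = FALSE)
  if (start_week < 1) stop("`start_week` must be >= 1", call. = FALSE)
  structure(list(release_ratio = release_ratio,
                 interval_weeks = as.integer(interval_weeks),
                 start_week = as.integer(start_week)),
            class = "release_schedule")
}

#' @export
print.release_schedule <- function(x, ...) {
  cat(sprintf("<release_schedule> ratio %.3g, every %d week(s) from release-phase week %d\n",
              x$release_ratio, x$interval_weeks, x$start_week))
  invisible(x)
}

round_half_up <- function(x) floor(x + 0.5)

#' Sterile males to release in a given week
#'
#' Zero on non-release weeks; on release weeks (weeks congruent to
#' `start_week` modulo `interval_weeks`),
#' `round(release_ratio x equilibrium_wild_males x release_multiplier x
#' interval_weeks)` (half-up rounding).
#'
#' @param schedule A [release_schedule()].
#' @param week Release-phase week index (1-based).
#' @param equilibrium_wild_males Equilibrium wild adult male count (> 0).
#' @param profile A [strain_profile()].
#' @return Integer count of males to release.
#' @examples
#' sch <- release_schedule(1, interval_weeks = 4)
#' weekly_release_count(sch, 1, 10000, strain_profiles("CcPub1_pgSIT"))
#' weekly_release_count(sch, 2, 10000, strain_profiles("CcPub1_pgSIT"))
#' @export
weekly_release_count <- function(schedule, week, equilibrium_wild_males,
                                 profile) {
  stopifnot(equilibrium_wild_males > 0, week >= 1)
  if (week < schedule$start_week ||
      (week - schedule$start_week) %% schedule$interval_weeks != 0) {
    return(0L)
  }
  as.integer(round_half_up(
    schedule$release_ratio * equilibrium_wild_males *
      profile$release_multiplier * schedule$interval_weeks
  ))
}

#' Build a release cohort
#'
#' Released individuals are always adult, male and sterile; they enter at
#' adult-emergence age with `weeks_adult = 0` and carry the profile's mating
#' fitness, then age and die along the male survival schedule like any other
#' adult male.
#'
#' @param count Number of males (>= 0).
#' @param profile A [strain_profile()].
#' @param config A [sim_config()] (sets the adult-emergence age).
#' @return A population tibble (empty for `count = 0`).
#' @examples
#' make_release_cohort(100, strain_profiles("standard_SIT"), sim_config())
#' @export
make_release_cohort <- function(count, profile, config) {
  stopifnot(count >= 0)
  if (count == 0) return(empty_population())
  population("released", "male", adult_age(config),
             weeks_adult = 0L, fitness = profile$male_mating_fitness,
             strain = profile$name, n = count)
}
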