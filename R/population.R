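# Population state and the weekly life cycle.
#
# The population is held as exchangeable equivalence classes: one row per
# (origin, sex, age, mating state, fitness, strain) combination with a count
# `n`. Class-level binomial / multinomial / Poisson draws are
# distributionally identical to per-individual draws, so all individual-based
# contracts hold while full-scale runs stay cheap.

POP_COLS <- c("origin", "sex", "age", "mating", "weeks_adult",
              "fitness", "strain", "n")

#' Life stage implied by age
#'
#' Wild flies are larvae for `larval_duration` weeks, pupae for
#' `pupal_duration` weeks, and adults thereafter. Released flies enter as
#' adults directly.
#'
#' @param age Age in weeks since egg; vectorised.
#' @param config A [sim_config()].
#' @return Character vector: `"larva"`, `"pupa"` or `"adult"`.
#' @export
stage_of <- function(age, config) {
  dplyr::case_when(
    age < config$larval_duration ~ "larva",
    age < adult_age(config) ~ "pupa",
    TRUE ~ "adult"
  )
}

#' Construct population rows
#'
#' Low-level constructor for equivalence-class rows of the population tibble.
#' Most users start from [stable_age_population()] or [make_release_cohort()]
#' instead.
#'
#' @param origin `"wild"` or `"released"`.
#' @param sex `"male"` or `"female"`.
#' @param age Age in weeks since egg.
#' @param mating Mating state for adult females (see [mating_states()]);
#'   `NA` otherwise.
#' @param weeks_adult Completed weeks as adult (0 in the first adult week);
#'   `NA` for juveniles.
#' @param fitness Relative male mating weight (1 for wild and genetic-sterile
#'   males, 0.83 for irradiated males).
#' @param strain Strain identifier for released flies; `NA` for wild.
#' @param n Count of individuals in the class.
#' @return A population tibble.
#' @export
population <- function(origin = "wild", sex = "female", age = 0L,
                       mating = NA_character_, weeks_adult = NA_integer_,
                       fitness = 1, strain = NA_character_, n = 0L) {
  tibble::tibble(
    origin = origin, sex = sex, age = as.integer(age),
    mating = mating, weeks_adult = as.integer(weeks_adult),
    fitness = as.numeric(fitness), strain = strain, n = as.numeric(n)
  )
}

empty_population <- function() population()[0, ]

# Fast tibble constructor for population rows (hot path; columns must be
# equal-length vectors in POP_COLS order).
pop_rows <- function(origin, sex, age, mating, weeks_adult, fitness, strain, n) {
  len <- length(n)
  structure(
    list(origin = rep_len(origin, len), sex = rep_len(sex, len),
         age = rep_len(as.integer(age), len),
         mating = rep_len(mating, len),
         weeks_adult = rep_len(as.integer(weeks_adult), len),
         fitness = rep_len(as.numeric(fitness), len),
         strain = rep_len(strain, len), n = as.numeric(n)),
    class = c("tbl_df", "tbl", "data.frame"),
    row.names = c(NA_integer_, -len)
  )
}

rbind_pop <- function(...) {
  parts <- Filter(function(p) !is.null(p) && nrow(p) > 0, list(...))
  if (length(parts) == 0) return(empty_population())
  cols <- lapply(POP_COLS, function(col) {
    unlist(lapply(parts, function(p) p[[col]]), use.names = FALSE)
  })
  names(cols) <- POP_COLS
  do.call(pop_rows, cols)
}

# Merge identical classes, drop empties, impose the canonical row order used
# for all random draws (replayability depends on this order).
compact_population <- function(pop) {
  keep <- pop$n > 0
  if (!all(keep)) pop <- pop[keep, , drop = FALSE]
  if (nrow(pop) == 0) return(empty_population())
  key <- paste(pop$origin, pop$sex, sprintf("%03d", pop$age), pop$mating,
               pop$fitness, pop$strain, sep = "\r")
  if (anyDuplicated(key)) {
    n_by <- rowsum(pop$n, key, reorder = FALSE)
    first <- !duplicated(key)
    pop <- pop[first, , drop = FALSE]
    pop$n <- as.numeric(n_by[match(key[first], rownames(n_by)), 1L])
    key <- key[first]
  }
  pop[order(key), , drop = FALSE]
}

is_adult <- function(pop, cfg) pop$age >= adult_age(cfg)

#' Analytic stable age structure of the no-release population
#'
#' Solves the mean-field equilibrium of the weekly life cycle: survivorship
#' from adult emergence under background x age-based survival, weekly per-sex
#' recruitment consistent with a target adult female count, the implied weekly
#' egg input, and the `expected_larvae` value that makes that egg input
#' stationary. All quantities are unscaled (scale_factor = 1).
#'
#' @param config A [sim_config()].
#' @return A list with elements `l_female`, `l_male` (survivorship from adult
#'   emergence), `recruits_per_sex` (weekly newly emerging adults of each sex),
#'   `eggs_eq` (weekly eggs at equilibrium), `f_star` (equilibrium competition
#'   factor), `expected_larvae`, `adult_females`, `adult_males`.
#' @keywords internal
stable_age_structure <- function(config) {
  bg <- config$adult_background_survival
  emerge <- adult_age(config)
  survivorship <- function(sched) {
    ages <- emerge:(length(sched) - 1L)
    l <- numeric(length(ages))
    l[1] <- 1
    for (i in seq_along(ages)[-1]) {
      l[i] <- l[i - 1] * bg * sched[ages[i - 1] + 1L]
    }
    stats::setNames(l, ages)
  }
  l_f <- survivorship(config$female_age_survival)
  l_m <- survivorship(config$male_age_survival)
  # reproduction starts in the second adult week
  repro_weight <- sum(l_f[-1])
  R <- config$init_adult_females / sum(l_f)
  eggs_eq <- config$poisson_mean_eggs * R * repro_weight
  # stationarity: eggs_eq * rate(f*) = 2R  (both sexes of recruits)
  rate_needed <- 2 * R / eggs_eq
  top <- config$base_larval_survival * config$beta
  if (rate_needed >= top) {
    stop("calibration error: required larval survival ", signif(rate_needed, 4),
         " exceeds the low-density maximum ", signif(top, 4),
         "; the configured demography cannot sustain the target population",
         call. = FALSE)
  }
  f_star <- (top / rate_needed - 1) / (config$beta - 1)
  list(
    l_female = l_f, l_male = l_m,
    recruits_per_sex = R,
    eggs_eq = eggs_eq,
    f_star = f_star,
    expected_larvae = eggs_eq / f_star,
    adult_females = config$init_adult_females,
    adult_males = R * sum(l_m)
  )
}

#' Initial population at the deterministic stable age distribution
#'
#' Builds the week-zero population used to start a run: juvenile cohorts in
#' the pupal pipeline and adults of both sexes spread over ages according to
#' the stable age distribution, scaled by `scale_factor`. Females past their
#' first adult week start as `first_fertile` (they mated under the abundant
#' wild males of the equilibrium); newly emerged females start as virgins.
#'
#' @param config A [sim_config()].
#' @return A population tibble.
#' @export
stable_age_population <- function(config) {
  eq <- stable_age_structure(config)
  s <- config$scale_factor
  emerge <- adult_age(config)
  R <- eq$recruits_per_sex * s

  juv_ages <- seq_len(emerge - 1L)  # age-0 rows exist only mid-week
  juv <- purrr::map_dfr(juv_ages, function(a) {
    dplyr::bind_rows(
      population("wild", "female", a, n = round(R)),
      population("wild", "male", a, n = round(R))
    )
  })

  adult_rows <- function(sex, l) {
    ages <- as.integer(names(l))
    purrr::map_dfr(seq_along(ages), function(i) {
      a <- ages[i]
      population(
        "wild", sex, a,
        mating = if (sex == "female") {
          if (a == emerge) "virgin" else "first_fertile"
        } else NA_character_,
        weeks_adult = a - emerge,
        n = round(R * l[i])
      )
    })
  }
  compact_population(dplyr::bind_rows(
    juv,
    adult_rows("female", eq$l_female),
    adult_rows("male", eq$l_male)
  ))
}

#' Weekly mating round
#'
#' At the beginning of each week mating takes place between adults. Every
#' virgin adult female mates once (males are sampled in proportion to
#' `count x fitness` via [select_mates()]); every previously mated female
#' remates with probability `remating_prob`, and her sperm-precedence state is
#' updated with [update_mating_state()]. Wild adult males are fertile;
#' released males are sterile. With no adult males present the round is a
#' no-op.
#'
#' @param pop Population tibble.
#' @param config A [sim_config()].
#' @return A list: `pop` (updated population) and `stats`, a one-row tibble
#'   with `matings`, `first_matings`, `rematings`, `mated_females`
#'   (denominator for the remating fraction), `rescued`, and `p_sterile` (the
#'   fitness-weighted sterile share of the male pool).
#' @export
weekly_mating_round <- function(pop, config) {
  pop <- compact_population(pop)
  adult <- is_adult(pop, config)
  male_idx <- which(adult & pop$sex == "male")
  males <- pop[male_idx, c("n", "fitness", "origin")]
  sterile_male <- males$origin == "released"
  weight <- sum(males$n * males$fitness)

  stats <- tibble::tibble(matings = 0, first_matings = 0, rematings = 0,
                          mated_females = 0, rescued = 0,
                          p_sterile = if (weight > 0) {
                            sum(males$n[sterile_male] * males$fitness[sterile_male]) / weight
                          } else NA_real_)

  fem_idx <- which(adult & pop$sex == "female")
  if (length(fem_idx) == 0 || weight == 0) {
    return(list(pop = pop, stats = stats))
  }

  new_state <- character(0)
  new_n <- numeric(0)
  new_from <- integer(0)
  for (i in fem_idx) {
    state <- pop$mating[i]
    n <- pop$n[i]
    if (state == "virgin") {
      mates <- select_mates(n, males)
      k_sterile <- sum(mates[sterile_male])
      stats$matings <- stats$matings + n
      stats$first_matings <- stats$first_matings + n
      pop$n[i] <- 0
      new_state <- c(new_state, "first_sterile", "first_fertile")
      new_n <- c(new_n, k_sterile, n - k_sterile)
      new_from <- c(new_from, i, i)
    } else {
      stats$mated_females <- stats$mated_females + n
      rem <- stats::rbinom(1L, n, config$remating_prob)
      stats$rematings <- stats$rematings + rem
      stats$matings <- stats$matings + rem
      if (state == "first_sterile" && rem > 0) {
        # only here can a remating change the state, so only here is the new
        # mate actually sampled
        mates <- select_mates(rem, males)
        k_fertile <- sum(mates[!sterile_male])
        if (k_fertile > 0) {
          stats$rescued <- stats$rescued + k_fertile
          pop$n[i] <- n - k_fertile
          new_state <- c(new_state, "sterile_rescued")
          new_n <- c(new_n, k_fertile)
          new_from <- c(new_from, i)
        }
      }
    }
  }
  keep <- new_n > 0
  new_rows <- pop_rows(pop$origin[new_from[keep]], "female",
                       pop$age[new_from[keep]], new_state[keep],
                       pop$weeks_adult[new_from[keep]],
                       pop$fitness[new_from[keep]],
                       pop$strain[new_from[keep]], new_n[keep])
  list(pop = compact_population(rbind_pop(pop, new_rows)), stats = stats)
}

#' Weekly reproduction
#'
#' Each mated adult female past her first adult week produces a clutch this
#' week with probability equal to her state fertility (1 for `first_fertile`,
#' `rescue_fertility` for `sterile_rescued`, 0 otherwise). Realised clutch
#' sizes are Poisson(`poisson_mean_eggs`); the weekly total is drawn as
#' Poisson(mean x clutches), exactly the distribution of the per-female sum.
#' Offspring sex is assigned independently 1:1.
#'
#' @param pop Population tibble (this week's mating round already applied).
#' @param config A [sim_config()].
#' @return A list: `eggs`, `eggs_female`, `eggs_male`, `clutches`, and the
#'   per-state accounting `eligible_fertile`, `producing_fertile`,
#'   `eligible_rescued`, `producing_rescued`.
#' @export
weekly_reproduction <- function(pop, config) {
  fem <- pop[is_adult(pop, config) & pop$sex == "female" &
               !is.na(pop$weeks_adult) & pop$weeks_adult >= 1, ]
  n_ff <- sum(fem$n[fem$mating == "first_fertile"])
  n_sr <- sum(fem$n[fem$mating == "sterile_rescued"])
  prod_sr <- if (n_sr > 0) stats::rbinom(1L, n_sr, config$rescue_fertility) else 0L
  clutches <- n_ff + prod_sr
  eggs <- if (clutches > 0) {
    stats::rpois(1L, config$poisson_mean_eggs * clutches)
  } else 0L
  eggs_f <- if (eggs > 0) stats::rbinom(1L, eggs, 0.5) else 0L
  list(
    eggs = eggs, eggs_female = eggs_f, eggs_male = eggs - eggs_f,
    clutches = clutches,
    eligible_fertile = n_ff, producing_fertile = n_ff,
    eligible_rescued = n_sr, producing_rescued = prod_sr
  )
}

#' Weekly mortality, aging and stage transitions
#'
#' Adults survive with probability
#' `adult_background_survival x age_survival_prob(age, sex)`; juveniles carry
#' no weekly mortality (their only mortality is larval competition). All
#' survivors age one week; pupae reaching adult age become adults with
#' `weeks_adult = 0` (and virgin mating state for females); existing adults
#' increment `weeks_adult`.
#'
#' @param pop Population tibble (this week's reproduction already applied;
#'   include the new age-0 larval cohort so it ages into the pupal stage).
#' @param config A [sim_config()].
#' @return Updated population tibble with a `deaths` attribute (a tibble of
#'   the pre-step classes, survivor and death counts).
#' @export
apply_mortality_and_aging <- function(pop, config) {
  pop <- compact_population(pop)
  if (nrow(pop) == 0) return(pop)
  adult <- is_adult(pop, config)
  p <- rep(1, nrow(pop))
  p[adult] <- config$adult_background_survival *
    age_survival_prob(pop$age[adult], pop$sex[adult],
                      config$male_age_survival, config$female_age_survival)
  survivors <- vapply(seq_len(nrow(pop)), function(i) {
    if (p[i] >= 1) pop$n[i]
    else if (p[i] <= 0) 0
    else as.numeric(stats::rbinom(1L, pop$n[i], p[i]))
  }, numeric(1))

  deaths <- tibble::tibble(
    origin = pop$origin, sex = pop$sex, age = pop$age, mating = pop$mating,
    n_before = pop$n, survivors = survivors, deaths = pop$n - survivors
  )

  pop$n <- survivors
  was_adult <- adult
  pop$age <- pop$age + 1L
  now_adult <- is_adult(pop, config)
  newly <- now_adult & !was_adult
  pop$weeks_adult[was_adult] <- pop$weeks_adult[was_adult] + 1L
  pop$weeks_adult[newly] <- 0L
  pop$mating[newly & pop$sex == "female"] <- "virgin"

  out <- compact_population(pop)
  attr(out, "deaths") <- deaths
  out
}

#' Advance the population one week
#'
#' Runs the full weekly cycle in the fixed event order: (1) inject the release
#' cohort, (2) mating round, (3) reproduction, (4) larval competition on this
#' week's eggs, (5) mortality, aging and stage transitions. Density dependence
#' therefore acts exactly once per clutch cohort.
#'
#' @param pop Population tibble at the start of the week.
#' @param config A [sim_config()] with `expected_larvae` set.
#' @param releases Optional release cohort (see [make_release_cohort()]).
#' @return A list: `pop` (end-of-week population) and `record`, a one-row
#'   tibble of weekly counts (adult wild females/males, released males alive,
#'   juveniles by stage, eggs laid, larvae surviving competition, matings,
#'   rematings, releases, and the total wild population).
#' @export
sim_week <- function(pop, config, releases = NULL) {
  released_n <- if (is.null(releases)) 0 else sum(releases$n)
  if (released_n > 0) pop <- rbind_pop(pop, releases)

  m <- weekly_mating_round(pop, config)
  r <- weekly_reproduction(m$pop, config)

  scaled_expected <- config$expected_larvae * config$scale_factor
  rate <- larval_survival_rate(r$eggs, scaled_expected,
                               config$beta, config$base_larval_survival)
  surv_f <- if (r$eggs_female > 0) stats::rbinom(1L, r$eggs_female, rate) else 0L
  surv_m <- if (r$eggs_male > 0) stats::rbinom(1L, r$eggs_male, rate) else 0L

  larvae <- pop_rows(c("wild", "wild"), c("female", "male"), c(0L, 0L),
                     NA_character_, NA_integer_, 1, NA_character_,
                     c(surv_f, surv_m))
  pop2 <- apply_mortality_and_aging(rbind_pop(m$pop, larvae), config)

  adult <- is_adult(pop2, config)
  wild <- pop2$origin == "wild"
  record <- tibble::tibble(
    wild_females = sum(pop2$n[adult & wild & pop2$sex == "female"]),
    wild_males = sum(pop2$n[adult & wild & pop2$sex == "male"]),
    released_males = sum(pop2$n[pop2$origin == "released"]),
    larvae = as.numeric(surv_f + surv_m),
    pupae = sum(pop2$n[wild & stage_of(pop2$age, config) == "pupa"]),
    eggs_laid = as.numeric(r$eggs),
    larvae_surviving = as.numeric(surv_f + surv_m),
    matings = m$stats$matings,
    rematings = m$stats$rematings,
    released_this_week = as.numeric(released_n),
    wild_total = sum(pop2$n[wild])
  )
  list(pop = pop2, record = record)
}
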