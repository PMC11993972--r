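# Density-dependent larval survival and age-based adult survival.

#' Beverton-Holt density-dependent larval survival rate
#'
#' Weekly egg-to-pupa survival of a larval cohort as a saturating function of
#' crowding:
#' \deqn{s(f) = s_1 \cdot \beta / ((\beta - 1) f + 1)}
#' where `f = n_larvae / expected_larvae` is the competition factor (1 at
#' carrying-capacity density), `beta` the low-density growth rate, and
#' `s_1 = base_larval_survival` the survival at f = 1. At zero density the
#' rate is exactly `beta` times the carrying-capacity rate.
#'
#' @param n_larvae Number of larvae competing this week (>= 0); vectorised.
#' @param expected_larvae Larval count at which f = 1 (> 0).
#' @param beta Low-density growth rate (>= 1).
#' @param base_larval_survival Survival probability at f = 1.
#' @return Survival probability (same length as `n_larvae`), in
#'   `(0, base_larval_survival * beta]`, strictly decreasing in `n_larvae`.
#' @examples
#' larval_survival_rate(0, 1e5)                 # low-density limit: 10x base
#' larval_survival_rate(1e5, 1e5)               # = 0.3344/9.373
#' @export
larval_survival_rate <- function(n_larvae, expected_larvae, beta = 10,
                                 base_larval_survival = 0.3344 / 9.373) {
  if (!is.numeric(expected_larvae) || length(expected_larvae) != 1 ||
      is.na(expected_larvae) || expected_larvae <= 0) {
    stop("`expected_larvae` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(beta) || length(beta) != 1 || is.na(beta) || beta < 1) {
    stop("`beta` must be a single number >= 1", call. = FALSE)
  }
  if (!is.numeric(n_larvae) || anyNA(n_larvae) || any(n_larvae < 0)) {
    stop("`n_larvae` must be non-negative", call. = FALSE)
  }
  f <- n_larvae / expected_larvae
  base_larval_survival * beta / ((beta - 1) * f + 1)
}

#' Age-based conditional weekly survival probability
#'
#' Looks up the sex-specific survival schedule at a given age (weeks since
#' egg). Ages beyond the end of a schedule return 0: no female survives past
#' age 12 -> 13 and no male past age 18 -> 19.
#'
#' @param age Age in weeks (>= 0); vectorised.
#' @param sex `"male"` or `"female"` (recycled against `age`).
#' @param male_age_survival,female_age_survival Survival schedules; defaults
#'   are the published ones.
#' @return Vector of survival probabilities.
#' @examples
#' age_survival_prob(2, "male")    # juvenile: 1
#' age_survival_prob(5, "female")  # 7/8
#' age_survival_prob(18, "male")   # 0
#' @export
age_survival_prob <- function(age, sex,
                              male_age_survival = default_male_survival(),
                              female_age_survival = default_female_survival()) {
  if (!is.numeric(age) || anyNA(age) || any(age < 0)) {
    stop("`age` must be non-negative", call. = FALSE)
  }
  if (!all(sex %in% c("male", "female"))) {
    stop('`sex` must be "male" or "female"', call. = FALSE)
  }
  n <- max(length(age), length(sex))
  age <- rep_len(as.integer(age), n)
  sex <- rep_len(sex, n)
  out <- numeric(n)
  male <- sex == "male"
  sched_at <- function(sched, a) {
    p <- rep(0, length(a))
    ok <- a < length(sched)
    p[ok] <- sched[a[ok] + 1L]
    p
  }
  out[male] <- sched_at(male_age_survival, age[male])
  out[!male] <- sched_at(female_age_survival, age[!male])
  out
}

#' Stochastic larval competition
#'
#' Draws the number of larvae surviving density-dependent competition:
#' survivors ~ Binomial(egg_count, [larval_survival_rate()] at that egg
#' count).
#'
#' @param egg_count Eggs (= larvae) entering the weekly larval pool (>= 0).
#' @param config A [sim_config()]; `config$expected_larvae` must be set
#'   (calibrated) and is scaled by `config$scale_factor`.
#' @return Integer count of survivors, <= `egg_count`.
#' @export
apply_larval_competition <- function(egg_count, config) {
  stopifnot(egg_count >= 0)
  if (is.null(config$expected_larvae)) {
    stop("`config$expected_larvae` is not set; calibrate first (see calibrate_equilibrium)",
         call. = FALSE)
  }
  if (egg_count == 0) return(0L)
  rate <- larval_survival_rate(
    egg_count, config$expected_larvae * config$scale_factor,
    config$beta, config$base_larval_survival
  )
  stats::rbinom(1L, egg_count, rate)
}
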