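# a minimal medfly_sim skeleton for metric tests
fake_sim <- function(release_females, horizon = 100L, eliminated = FALSE,
                     elim_week = NA_integer_) {
  structure(
    list(
      trajectory = tibble::tibble(
        phase = "release", week = seq_along(release_females),
        wild_females = release_females
      ),
      config = sim_config(horizon_weeks = horizon),
      profile = strain_profiles("standard_SIT"),
      schedule = release_schedule(1),
      seed = 1L, equilibrium_wild_males = 1,
      expected_larvae = 1, eliminated = eliminated,
      elimination_week = elim_week
    ),
    class = "medfly_sim"
  )
}

test_that("analytic calibration solves the stationarity condition", {
  cal <- calibrate_equilibrium(sim_config(), pilot = FALSE)
  expect_gt(cal$expected_larvae, 0)
  expect_true(cal$f_star > 0 && cal$f_star < 1)
  # at the calibrated point, weekly recruitment balances the stable age
  # distribution: eggs x rate(f*) = 2 x weekly recruits per sex
  eq <- medflysit:::stable_age_structure(sim_config())
  rate <- larval_survival_rate(eq$eggs_eq, cal$expected_larvae)
  expect_equal(eq$eggs_eq * rate, 2 * eq$recruits_per_sex, tolerance = 1e-10)
  # male equilibrium exceeds female (males live longer)
  expect_gt(cal$equilibrium_wild_males, 50000)
})

test_that("pilot calibration holds the micro population near its target", {
  cal <- calibrate_equilibrium(fixture_scenario("micro"), pilot = TRUE,
                               seed = 21)
  expect_lt(abs(cal$pilot_mean_females - 100) / 100, 0.3)
  expect_gt(cal$equilibrium_wild_males, 0)
})

test_that("equilibrium size increases with expected_larvae", {
  cfg <- fixture_scenario("micro", burn_in_weeks = 40, horizon_weeks = 1)
  cfg <- calibrated(cfg)
  cfg2 <- cfg
  cfg2$expected_larvae <- cfg$expected_larvae * 2
  mean_tail <- function(cf, seed) {
    sim <- run_simulation(cf, schedule = release_schedule(0), seed = seed)
    tr <- tidy(sim)
    mean(utils::tail(tr$wild_females[tr$phase == "burn_in"], 15))
  }
  base <- mean(vapply(31:33, function(s) mean_tail(cfg, s), numeric(1)))
  doubled <- mean(vapply(31:33, function(s) mean_tail(cfg2, s), numeric(1)))
  expect_gt(doubled, 1.5 * base)
})

test_that("identical seed and configuration replay bit-identical trajectories", {
  cfg <- calibrated(tiny_config())
  a <- run_simulation(cfg, strain_profiles("CcPub1_pgSIT"),
                      release_schedule(1), seed = 99)
  b <- run_simulation(cfg, strain_profiles("CcPub1_pgSIT"),
                      release_schedule(1), seed = 99)
  expect_identical(tidy(a), tidy(b))
  c <- run_simulation(cfg, strain_profiles("CcPub1_pgSIT"),
                      release_schedule(1), seed = 100)
  expect_false(identical(tidy(a), tidy(c)))
})

test_that("a no-release run stays stationary at desk scale", {
  cfg <- calibrated(fixture_scenario("desk", horizon_weeks = 1))
  means <- vapply(1:5, function(s) {
    sim <- run_simulation(cfg, schedule = release_schedule(0), seed = 50 + s)
    tr <- tidy(sim)
    mean(utils::tail(tr$wild_females[tr$phase == "burn_in"], 20))
  }, numeric(1))
  expect_lt(abs(mean(means) - 5000) / 5000, 0.1)
})

test_that("elimination time is censored at the horizon", {
  censored <- fake_sim(rep(400, 100))
  tte <- time_to_elimination(censored)
  expect_equal(as.integer(tte), 100L)
  expect_true(attr(tte, "censored"))

  done <- fake_sim(c(rep(10, 59), 0), eliminated = TRUE, elim_week = 60L)
  tte2 <- time_to_elimination(done)
  expect_equal(as.integer(tte2), 60L)
  expect_false(attr(tte2, "censored"))
})

test_that("the last-20-weeks female mean pads eliminated weeks with zeros", {
  expect_equal(mean_females_last20(fake_sim(rep(7, 100))), 7)
  # eliminated before week 81: all of the window is zeros
  early <- fake_sim(c(rep(50, 69), 0), eliminated = TRUE, elim_week = 70L)
  expect_equal(mean_females_last20(early), 0)
  # partial overlap: 9 observed weeks at 6 females, then zeros
  mid <- fake_sim(c(rep(3, 80), rep(6, 9), 0), eliminated = TRUE,
                  elim_week = 90L)
  expect_equal(mean_females_last20(mid), sum(rep(6, 9)) / 20)
})

test_that("glance returns the run in one tidy row", {
  cfg <- calibrated(tiny_config())
  sim <- run_simulation(cfg, strain_profiles("DmPub2_pgSIT"),
                        release_schedule(2), seed = 7)
  g <- glance(sim)
  expect_equal(nrow(g), 1)
  expect_identical(g$system, "DmPub2_pgSIT")
  expect_equal(g$release_ratio, 2)
  expect_identical(g$censored, !g$eliminated)
  tr <- tidy(sim)
  expect_identical(names(tr)[1:2], c("phase", "week"))
  expect_true(all(tr$wild_total >= 0))
})

test_that("trajectories record releases on schedule", {
  cfg <- calibrated(tiny_config())
  sim <- run_simulation(cfg, strain_profiles("standard_SIT"),
                        release_schedule(1, interval_weeks = 3), seed = 17)
  rel <- tidy(sim)[tidy(sim)$phase == "release", ]
  expect_true(all(rel$released_this_week[rel$week %% 3 == 1] > 0))
  expect_true(all(rel$released_this_week[rel$week %% 3 != 1] == 0))
  expect_true(all(tidy(sim)$released_this_week[tidy(sim)$phase == "burn_in"] == 0))
})
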