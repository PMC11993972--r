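test_that("life stage follows age and the stage durations", {
  cfg <- sim_config()  # larva 1 wk, pupa 2 wk
  expect_identical(stage_of(c(0, 1, 2, 3, 10), cfg),
                   c("larva", "pupa", "pupa", "adult", "adult"))
  cfg2 <- sim_config(larval_duration = 2, pupal_duration = 3)
  expect_identical(stage_of(c(1, 2, 4, 5), cfg2),
                   c("larva", "pupa", "pupa", "adult"))
})

test_that("mortality kills females at age 12 and males at age 18 surely", {
  cfg <- sim_config()
  pop <- dplyr::bind_rows(
    population("wild", "female", 12L, "first_fertile", 9L, n = 500),
    population("wild", "male", 18L, weeks_adult = 15L, n = 500)
  )
  set.seed(1)
  out <- apply_mortality_and_aging(pop, cfg)
  expect_equal(nrow(out), 0)
})

test_that("adults in the flat schedule region die only from background causes", {
  cfg <- sim_config()
  n <- 50000
  pop <- population("wild", "male", 4L, weeks_adult = 1L, n = n)
  set.seed(2)
  out <- apply_mortality_and_aging(pop, cfg)
  se <- sqrt(0.9 * 0.1 / n)
  expect_lt(abs(sum(out$n) / n - 0.9), 3 * se)
})

test_that("deaths and survivors add up per class", {
  cfg <- sim_config()
  set.seed(3)
  pop <- stable_age_population(fixture_scenario("micro"))
  out <- apply_mortality_and_aging(pop, cfg)
  deaths <- attr(out, "deaths")
  expect_equal(deaths$survivors + deaths$deaths, deaths$n_before)
  expect_equal(sum(deaths$n_before), sum(pop$n))
  expect_equal(sum(out$n), sum(deaths$survivors))
})

test_that("juveniles survive, age and transition with correct bookkeeping", {
  cfg <- sim_config()
  pop <- dplyr::bind_rows(
    population("wild", "female", 0L, n = 40),                 # larva
    population("wild", "female", 2L, n = 30),                 # last pupal week
    population("wild", "male", 2L, n = 20)
  )
  set.seed(4)
  out <- apply_mortality_and_aging(pop, cfg)
  expect_equal(sum(out$n), 90)  # no juvenile mortality here
  new_ad_f <- out[out$age == 3 & out$sex == "female", ]
  expect_equal(new_ad_f$weeks_adult, 0L)
  expect_identical(new_ad_f$mating, "virgin")
  new_ad_m <- out[out$age == 3 & out$sex == "male", ]
  expect_equal(new_ad_m$weeks_adult, 0L)
  expect_identical(out$age[out$sex == "female" & out$n == 40], 1L)
})

test_that("reproduction skips the first adult week and gates on fertility", {
  cfg <- sim_config()
  first_week <- adult_females(1000, "first_fertile", weeks_adult = 0L)
  expect_equal(weekly_reproduction(first_week, cfg)$eggs, 0)

  sterile <- adult_females(1000, "first_sterile", weeks_adult = 3L)
  expect_equal(weekly_reproduction(sterile, cfg)$eggs, 0)

  set.seed(6)
  fertile <- adult_females(1000, "first_fertile", weeks_adult = 3L)
  out <- weekly_reproduction(fertile, cfg)
  expect_equal(out$clutches, 1000)
  expect_equal(out$eggs_female + out$eggs_male, out$eggs)
  expect_gt(out$eggs, 0)
  # sexes split 1:1
  expect_lt(abs(out$eggs_female / out$eggs - 0.5), 3 * sqrt(0.25 / out$eggs))
})

test_that("rescued females produce clutches at half the fertile rate", {
  cfg <- sim_config()
  n <- 20000
  set.seed(8)
  out <- weekly_reproduction(dplyr::bind_rows(
    adult_females(n, "first_fertile"), adult_females(n, "sterile_rescued")
  ), cfg)
  expect_equal(out$producing_fertile, n)
  ratio <- (out$producing_rescued / out$eligible_rescued) /
    (out$producing_fertile / out$eligible_fertile)
  se <- sqrt(0.5 * 0.5 / n)
  expect_lt(abs(ratio - 0.5), 3 * se)
})

test_that("clutch sizes average the configured Poisson mean", {
  cfg <- sim_config()
  set.seed(10)
  out <- weekly_reproduction(adult_females(50000, "first_fertile"), cfg)
  se <- sqrt(9.37 / out$clutches)
  expect_lt(abs(out$eggs / out$clutches - 9.37), 3 * se)
})

test_that("released males sire nothing: only wild eggs ever enter the pool", {
  cfg <- calibrated(tiny_config())
  pop <- dplyr::bind_rows(
    adult_females(100, "virgin", weeks_adult = 0L),
    adult_males(1000, origin = "released", strain = "standard_SIT",
                fitness = 0.83)
  )
  set.seed(12)
  wk <- sim_week(pop, cfg)
  expect_equal(wk$record$eggs_laid, 0)
  # after two more weeks the (now first_sterile, older) females still lay none
  for (i in 1:2) wk <- sim_week(wk$pop, cfg)
  expect_equal(wk$record$eggs_laid, 0)
  expect_identical(unique(wk$pop$origin[wk$pop$age < 3]), character(0))
})

test_that("a full week conserves individuals outside birth and death", {
  cfg <- calibrated(fixture_scenario("micro"))
  set.seed(13)
  pop <- stable_age_population(cfg)
  wk <- sim_week(pop, cfg)
  # all counts non-negative and stages consistent with ages
  expect_true(all(wk$pop$n >= 0))
  expect_true(all(wk$pop$age[!is.na(wk$pop$weeks_adult)] >= 3))
  # adult female mating states are always set, juveniles never
  adult_f <- wk$pop$sex == "female" & wk$pop$age >= 3
  expect_false(anyNA(wk$pop$mating[adult_f]))
  expect_true(all(is.na(wk$pop$mating[wk$pop$age < 3])))
})

test_that("no female exceeds age 12 and no male age 18 over a long run", {
  cfg <- calibrated(fixture_scenario("micro", burn_in_weeks = 40,
                                     horizon_weeks = 20))
  sim <- run_simulation(cfg, strain_profiles("standard_SIT"),
                        release_schedule(0.5), seed = 42)
  pop <- sim$final_population
  expect_lte(max(pop$age[pop$sex == "female"], -Inf), 12)
  expect_lte(max(pop$age[pop$sex == "male"], -Inf), 18)
})
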