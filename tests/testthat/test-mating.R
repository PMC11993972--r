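test_that("sperm-precedence transitions match exhaustive enumeration", {
  # oracle: the full 8-case transition table written out by hand
  oracle <- tibble::tribble(
    ~from,             ~sterile_mate, ~to,
    "virgin",          TRUE,          "first_sterile",
    "virgin",          FALSE,         "first_fertile",
    "first_fertile",   TRUE,          "first_fertile",
    "first_fertile",   FALSE,         "first_fertile",
    "first_sterile",   TRUE,          "first_sterile",
    "first_sterile",   FALSE,         "sterile_rescued",
    "sterile_rescued", TRUE,          "sterile_rescued",
    "sterile_rescued", FALSE,         "sterile_rescued"
  )
  got <- update_mating_state(oracle$from, oracle$sterile_mate)
  expect_identical(got, oracle$to)
  expect_error(update_mating_state("widowed", TRUE), "unknown")
})

test_that("mating states carry the stated fertilities and never regress", {
  expect_equal(mating_fertility(mating_states()), c(0, 1, 0, 0.5))
  expect_equal(mating_fertility("sterile_rescued", rescue_fertility = 0.25),
               0.25)
  expect_error(mating_fertility("bereft"), "unknown")

  # property: along any random mating history, fertility rank never returns
  # to virgin and first_fertile is absorbing
  rank <- c(virgin = 0, first_sterile = 1, sterile_rescued = 2,
            first_fertile = 3)
  set.seed(7)
  for (rep in 1:50) {
    state <- "virgin"
    for (step in 1:12) {
      nxt <- update_mating_state(state, runif(1) < 0.5)
      expect_true(nxt != "virgin")
      if (state == "first_fertile") expect_identical(nxt, "first_fertile")
      if (state == "sterile_rescued") expect_identical(nxt, "sterile_rescued")
      if (state == "first_sterile") {
        expect_true(nxt %in% c("first_sterile", "sterile_rescued"))
      }
      state <- nxt
    }
  }
})

test_that("mate selection is proportional to count x fitness", {
  one_male <- tibble::tibble(n = 1, fitness = 0.4)
  expect_identical(select_mates(25, one_male), 25L)

  # irradiated males at fitness 0.83 against equal numbers of wild males take
  # a 0.83/1.83 share of matings
  males <- tibble::tibble(n = c(5000, 5000), fitness = c(1, 0.83))
  set.seed(11)
  k <- 200000
  got <- select_mates(k, males)
  expect_identical(sum(got), as.integer(k))
  p <- 0.83 / 1.83
  se <- sqrt(p * (1 - p) / k)
  expect_lt(abs(got[2] / k - p), 3 * se)

  # equal fitness: uniform shares within sampling error
  males_eq <- tibble::tibble(n = c(3000, 3000), fitness = c(1, 1))
  got_eq <- select_mates(k, males_eq)
  expect_lt(abs(got_eq[1] / k - 0.5), 3 * sqrt(0.25 / k))

  # empty or weightless pools are valid no-ops
  expect_identical(select_mates(10, tibble::tibble(n = numeric(),
                                                   fitness = numeric())),
                   integer(0))
  expect_identical(select_mates(10, tibble::tibble(n = 0, fitness = 1)),
                   integer(1))
})

test_that("a mating round with no adult males changes nothing", {
  cfg <- sim_config()
  pop <- dplyr::bind_rows(adult_females(50, "virgin"), adult_females(30, "first_sterile"))
  out <- weekly_mating_round(pop, cfg)
  expect_equal(sum(out$pop$n[out$pop$mating == "virgin"]), 50)
  expect_equal(sum(out$pop$n[out$pop$mating == "first_sterile"]), 30)
  expect_equal(out$stats$matings, 0)
})

test_that("virgins facing only sterile males all become first_sterile", {
  cfg <- sim_config()
  pop <- dplyr::bind_rows(adult_females(200, "virgin"),
               adult_males(500, origin = "released", fitness = 1,
                           strain = "CcPub1_pgSIT"))
  set.seed(3)
  out <- weekly_mating_round(pop, cfg)
  fem <- out$pop[out$pop$sex == "female", ]
  expect_identical(unique(fem$mating), "first_sterile")
  expect_equal(sum(fem$n), 200)
  expect_equal(out$stats$p_sterile, 1)
})

test_that("the weekly remating fraction recovers 1/3", {
  cfg <- sim_config()
  n_mated <- 30000
  pop <- dplyr::bind_rows(adult_females(n_mated, "first_fertile"), adult_males(5000))
  set.seed(5)
  out <- weekly_mating_round(pop, cfg)
  expect_equal(out$stats$mated_females, n_mated)
  se <- sqrt((1 / 3) * (2 / 3) / n_mated)
  expect_lt(abs(out$stats$rematings / n_mated - 1 / 3), 3 * se)
})

test_that("rescue happens at the fertile share of remating draws", {
  cfg <- sim_config()
  n <- 30000
  pop <- dplyr::bind_rows(adult_females(n, "first_sterile"),
               adult_males(4000, origin = "wild"),
               adult_males(4000, origin = "released", fitness = 1,
                           strain = "CcPub1_pgSIT"))
  set.seed(9)
  out <- weekly_mating_round(pop, cfg)
  # P(rescued this week) = remating_prob x fertile weight share = 1/3 x 1/2
  p <- (1 / 3) * 0.5
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(out$stats$rescued / n - p), 3 * se)
  states <- out$pop$mating[out$pop$sex == "female"]
  expect_setequal(states, c("first_sterile", "sterile_rescued"))
})
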