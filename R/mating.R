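# Sperm-precedence state machine and fitness-weighted mate selection.

#' Sperm-precedence mating states
#'
#' Female medflies are polyandrous but use sperm from their first mate
#' preferentially. The model tracks each female in one of four states:
#' \describe{
#'   \item{`virgin`}{never mated; fertility 0.}
#'   \item{`first_fertile`}{first mate was fertile; fertility 1, unaffected by
#'     any later mating.}
#'   \item{`first_sterile`}{first mate was sterile; fertility 0.}
#'   \item{`sterile_rescued`}{first mate sterile, then remated with a fertile
#'     male; each week the whole clutch is produced with probability 0.5.}
#' }
#' Transitions are monotone: `first_fertile` and `sterile_rescued` are
#' absorbing, and `first_sterile` can only move to `sterile_rescued`.
#'
#' @return Character vector of the four state names.
#' @export
mating_states <- function() {
  c("virgin", "first_fertile", "first_sterile", "sterile_rescued")
}

#' Weekly clutch probability implied by a mating state
#'
#' @param state Character vector of states from [mating_states()].
#' @param rescue_fertility Clutch probability in the `sterile_rescued` state.
#' @return Numeric vector of weekly clutch probabilities.
#' @examples
#' mating_fertility(mating_states())
#' @export
mating_fertility <- function(state, rescue_fertility = 0.5) {
  if (!all(state %in% mating_states())) {
    stop("unknown mating state", call. = FALSE)
  }
  unname(c(virgin = 0, first_fertile = 1, first_sterile = 0,
           sterile_rescued = rescue_fertility)[state])
}

#' Update a female's sperm-precedence state after a mating
#'
#' A virgin takes the fertility of her first mate. A female whose first mate
#' was fertile is unaffected by later matings. A female whose first mate was
#' sterile is "rescued" to 50% fertility by a later fertile mate; further
#' sterile matings change nothing.
#'
#' @param current Character vector of current states (see [mating_states()]).
#' @param male_is_sterile Logical vector: is this week's mate sterile?
#' @return Character vector of updated states.
#' @examples
#' update_mating_state("virgin", TRUE)           # first_sterile
#' update_mating_state("first_sterile", FALSE)   # sterile_rescued
#' update_mating_state("first_fertile", TRUE)    # first_fertile
#' @export
update_mating_state <- function(current, male_is_sterile) {
  if (!all(current %in% mating_states())) {
    stop("unknown mating state", call. = FALSE)
  }
  n <- max(length(current), length(male_is_sterile))
  current <- rep_len(current, n)
  sterile <- rep_len(as.logical(male_is_sterile), n)
  out <- current
  out[current == "virgin"] <- ifelse(sterile[current == "virgin"],
                                     "first_sterile", "first_fertile")
  rescue <- current == "first_sterile" & !sterile
  out[rescue] <- "sterile_rescued"
  out
}

#' Fitness-weighted mate selection
#'
#' Assigns each of `n_matings` mating females one male for the week, sampled
#' independently (with replacement across females) with probability
#' proportional to `count x mating_fitness` of each male class.
#'
#' @param n_matings Number of females mating this week.
#' @param males A data frame of male classes with columns `n` (count) and
#'   `fitness` (relative mating weight).
#' @return Integer vector: matings assigned to each male class (row of
#'   `males`). All zeros (with a warning-free no-op) if no males are present.
#' @examples
#' males <- tibble::tibble(n = c(100, 100), fitness = c(1, 0.83))
#' set.seed(1)
#' select_mates(1000, males)
#' @export
select_mates <- function(n_matings, males) {
  k <- nrow(males)
  if (k == 0 || n_matings == 0 || sum(males$n) == 0) {
    return(integer(max(k, 0)))
  }
  w <- males$n * males$fitness
  if (sum(w) == 0) return(integer(k))
  as.integer(stats::rmultinom(1L, size = n_matings, prob = w))
}
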