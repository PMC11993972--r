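# Computational experiments: factorial grids over systems, release ratios and
# release intervals, with replicates and summaries.

#' Define an experiment grid
#'
#' A factorial design over release systems, release ratios and release
#' intervals, each cell replicated with paired seeds (`base_seed + 1:replicates`
#' reused across cells, which sharpens between-condition comparisons).
#'
#' @param systems Character vector of [strain_profiles()] names.
#' @param ratios Numeric vector of release ratios.
#' @param intervals Integer vector of release intervals (weeks).
#' @param replicates Replicates per cell (>= 1).
#' @param base_seed Base RNG seed.
#' @return A tibble of class `medfly_grid` with one row per run.
#' @examples
#' experiment_grid(c("standard_SIT", "CcPub1_pgSIT"), ratios = c(0.5, 1, 2),
#'                 replicates = 3)
#' @export
experiment_grid <- function(systems = names(strain_profiles()),
                            ratios = 1, intervals = 1L,
                            replicates = 5L, base_seed = 1L) {
  stopifnot(length(systems) > 0, length(ratios) > 0, length(intervals) > 0,
            replicates >= 1)
  bad <- setdiff(systems, names(strain_profiles()))
  if (length(bad)) {
    stop("unknown system(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  grid <- tidyr::expand_grid(
    system = systems, release_ratio = ratios,
    interval_weeks = as.integer(intervals),
    replicate = seq_len(replicates)
  )
  grid$seed <- as.integer(base_seed) + grid$replicate
  class(grid) <- c("medfly_grid", class(grid))
  grid
}

#' Run every cell of an experiment grid
#'
#' Runs [run_simulation()] for each (system, ratio, interval, replicate) row.
#' Failed runs are recorded with an error status and the grid continues.
#'
#' @param grid From [experiment_grid()].
#' @param config A [sim_config()]; calibrated analytically once if
#'   `expected_larvae` is `NULL`, so every run shares the same calibration.
#' @param keep_trajectories Keep each run's full trajectory in a list column?
#' @param verbose Print a progress line per run?
#' @return A tibble of class `medfly_grid_results`: the grid columns plus
#'   `eliminated`, `elimination_week`, `censored`, `mean_females_last20`,
#'   `equilibrium_wild_males`, `status`, and (optionally) `trajectory`.
#' @examples
#' \donttest{
#' cfg <- fixture_scenario("micro", burn_in_weeks = 10, horizon_weeks = 10)
#' res <- run_grid(experiment_grid("standard_SIT", replicates = 2), cfg)
#' summarize_grid(res)
#' }
#' @export
run_grid <- function(grid, config, keep_trajectories = FALSE, verbose = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(config$expected_larvae)) {
    config$expected_larvae <- stable_age_structure(config)$expected_larvae
  }
  runs <- purrr::pmap(
    list(grid$system, grid$release_ratio, grid$interval_weeks, grid$seed),
    function(system, ratio, interval, seed) {
      res <- tryCatch({
        sim <- run_simulation(
          config, strain_profiles(system),
          release_schedule(ratio, interval_weeks = interval), seed = seed
        )
        row <- glance(sim)
        row$status <- "ok"
        if (keep_trajectories) row$trajectory <- list(tidy(sim))
        row
      }, error = function(e) {
        tibble::tibble(
          system = system, release_ratio = ratio, interval_weeks = interval,
          seed = seed, equilibrium_wild_males = NA_real_, eliminated = NA,
          elimination_week = NA_integer_, censored = NA,
          mean_females_last20 = NA_real_, status = conditionMessage(e)
        )
      })
      if (verbose) {
        message(sprintf("%s ratio %.3g interval %d seed %d: %s", system,
                        ratio, interval, seed,
                        if (isTRUE(res$eliminated)) {
                          paste0("eliminated wk ", res$elimination_week)
                        } else "censored"))
      }
      res
    }
  )
  out <- dplyr::bind_rows(runs)
  out$replicate <- grid$replicate
  class(out) <- c("medfly_grid_results", class(out))
  out
}

#' Summarise grid results per condition
#'
#' Aggregates replicates per (system, ratio, interval): run counts, the
#' censoring fraction, the mean/sd of the elimination week over eliminating
#' runs only, and the mean/sd of the last-20-weeks female count over all runs.
#'
#' @param results From [run_grid()].
#' @return A tibble of class `medfly_grid_summary`, one row per condition.
#' @export
summarize_grid <- function(results) {
  if (nrow(results) == 0) stop("empty results", call. = FALSE)
  ok <- results[results$status == "ok", ]
  out <- dplyr::summarise(
    dplyr::group_by(ok, .data$system, .data$release_ratio,
                    .data$interval_weeks),
    n = dplyr::n(),
    n_eliminated = sum(.data$eliminated),
    censoring_fraction = mean(.data$censored),
    mean_elimination_week = ifelse(
      any(.data$eliminated),
      mean(.data$elimination_week[.data$eliminated]), NA_real_),
    sd_elimination_week = ifelse(
      sum(.data$eliminated) > 1,
      stats::sd(.data$elimination_week[.data$eliminated]), NA_real_),
    mean_females_last20 = mean(.data$mean_females_last20),
    sd_females_last20 = ifelse(dplyr::n() > 1,
                               stats::sd(.data$mean_females_last20),
                               NA_real_),
    .groups = "drop"
  )
  class(out) <- c("medfly_grid_summary", class(out))
  out
}
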