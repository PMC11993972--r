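# Configuration files, result serialization and run manifests.

#' Load a run configuration from a YAML file
#'
#' The file may contain three top-level sections, all optional:
#' \describe{
#'   \item{`sim`}{any [sim_config()] field; omitted fields take the published
#'     defaults.}
#'   \item{`profile`}{either `name:` (a built-in from [strain_profiles()]) or
#'     the fields of [strain_profile()]; a radiation profile with fitness
#'     omitted defaults to 0.83.}
#'   \item{`schedule`}{fields of [release_schedule()].}
#' }
#' Unknown keys and out-of-range values raise errors naming the offending key.
#'
#' @param path Path to a YAML file. An empty file yields the full default
#'   parameter set.
#' @param overrides Named list applied on top of the file's `sim` section
#'   (used by the command-line interface for flag precedence).
#' @return A list: `config` ([sim_config()]), `profile` ([strain_profile()]),
#'   `schedule` ([release_schedule()]).
#' @export
load_config <- function(path, overrides = list()) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), c("sim", "profile", "schedule"))
  if (length(unknown)) {
    stop("unknown top-level config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }

  sim_args <- c(raw$sim %||% list(), overrides)
  sim_args <- sim_args[!duplicated(names(sim_args), fromLast = TRUE)]
  allowed <- names(formals(sim_config))
  unknown <- setdiff(names(sim_args), allowed)
  if (length(unknown)) {
    stop("unknown `sim` config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  config <- do.call(sim_config, sim_args)

  prof <- raw$profile %||% list(name = "standard_SIT")
  profile <- if (!is.null(prof$name) && length(prof) == 1) {
    strain_profiles(prof$name)
  } else {
    unknown <- setdiff(names(prof), names(formals(strain_profile)))
    if (length(unknown)) {
      stop("unknown `profile` config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    do.call(strain_profile, prof)
  }

  sch <- raw$schedule %||% list()
  unknown <- setdiff(names(sch), names(formals(release_schedule)))
  if (length(unknown)) {
    stop("unknown `schedule` config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  schedule <- do.call(release_schedule, sch)

  list(config = config, profile = profile, schedule = schedule)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Build a run manifest
#'
#' A manifest captures everything needed to reproduce a set of runs bit for
#' bit: the full configuration snapshot, the seeds, the package version,
#' timestamps, and the output files written.
#'
#' @param config A [sim_config()].
#' @param seeds Integer vector of seeds used.
#' @param outputs Character vector of result-file paths.
#' @param started,finished POSIXct timestamps.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(config, seeds, outputs = character(),
                         started = Sys.time(), finished = Sys.time()) {
  structure(
    list(
      package = "medflysit",
      version = as.character(utils::packageVersion("medflysit")),
      config = unclass(config),
      seeds = as.integer(seeds),
      outputs = outputs,
      started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
      finished = format(finished, "%Y-%m-%dT%H:%M:%S%z")
    ),
    class = "run_manifest"
  )
}

#' Write simulation results to disk
#'
#' Writes one trajectory CSV per run, a tidy grid-results CSV (if grid results
#' are given), a JSON summary, and a JSON manifest referencing every file.
#' Re-running with the same seeds and configuration reproduces identical CSV
#' bodies.
#'
#' @param sims A `medfly_sim`, or a list of them, or `NULL`.
#' @param results Optional [run_grid()] results tibble.
#' @param out_dir Output directory (created if missing).
#' @param config The [sim_config()] recorded in the manifest (defaults to the
#'   first sim's config).
#' @return Invisibly, the manifest (also written as `manifest.json`).
#' @export
write_results <- function(sims = NULL, results = NULL, out_dir,
                          config = NULL) {
  started <- Sys.time()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(sims, "medfly_sim")) sims <- list(sims)
  outputs <- character()
  seeds <- integer()

  for (sim in sims %||% list()) {
    f <- file.path(out_dir, sprintf("trajectory_%s_seed%d.csv",
                                    sim$profile$name, sim$seed))
    readr::write_csv(tidy(sim), f)
    outputs <- c(outputs, f)
    seeds <- c(seeds, sim$seed)
  }

  if (!is.null(results)) {
    f <- file.path(out_dir, "grid_results.csv")
    flat <- results[, setdiff(names(results), "trajectory")]
    readr::write_csv(flat, f)
    outputs <- c(outputs, f)
    seeds <- unique(c(seeds, results$seed))

    sf <- file.path(out_dir, "grid_summary.json")
    jsonlite::write_json(summarize_grid(results), sf, digits = NA,
                         pretty = TRUE)
    outputs <- c(outputs, sf)
  }

  if (is.null(config)) {
    config <- if (length(sims %||% list())) sims[[1]]$config else sim_config()
  }
  manifest <- run_manifest(config, seeds, outputs, started, Sys.time())
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(unclass(manifest), mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(manifest)
}
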