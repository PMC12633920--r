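# Config and results persistence. Configurations travel as YAML or JSON
# with one namespace per parameter block; results and trajectories as
# plain CSV so they can be reanalysed anywhere.

block_builders <- list(
  behaviour = behaviour_params,
  demography = demography_params,
  central_institution = institution_params,
  schedule = schedule_config
)

#' Load and validate a run configuration from YAML or JSON
#'
#' The file may contain any of the namespaces `behaviour`, `demography`,
#' `central_institution` and `schedule`, plus the top-level fields
#' `n_agents`, `space_size`, `threats_enabled`, `pb_enabled`, `max_pop` and
#' `seed`. Unset fields take their defaults (fixed constants and the
#' calibrated profile), unknown keys are rejected, and every value passes
#' the same validation as the constructors.
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return a [sim_config()]; the file's `seed` (if any) is attached as
#'   attribute `seed`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!is.list(raw)) stop("config file must parse to a mapping")
  top_known <- c("n_agents", "space_size", "threats_enabled", "pb_enabled",
                 "max_pop", "seed", names(block_builders))
  unknown <- setdiff(names(raw), top_known)
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  blocks <- list()
  for (nm in names(block_builders)) {
    builder <- block_builders[[nm]]
    given <- raw[[nm]]
    if (is.null(given)) given <- list()
    bad <- setdiff(names(given), names(formals(builder)))
    if (length(bad))
      stop(sprintf("unknown key(s) in '%s': %s", nm,
                   paste(bad, collapse = ", ")))
    if (nm == "central_institution" && length(given) &&
        is.null(given$ci_enabled))
      given$ci_enabled <- TRUE
    blocks[[nm]] <- do.call(builder, given)
  }
  args <- list(behaviour = blocks$behaviour, demography = blocks$demography,
               institutions = blocks$central_institution,
               schedule = blocks$schedule)
  for (nm in c("n_agents", "space_size", "threats_enabled", "pb_enabled",
               "max_pop"))
    if (!is.null(raw[[nm]])) args[[nm]] <- raw[[nm]]
  cfg <- do.call(sim_config, args)
  if (!is.null(raw$seed)) attr(cfg, "seed") <- as.integer(raw$seed)
  cfg
}

#' Serialise a configuration to YAML or JSON
#'
#' Writes every parameter block explicitly so that a round trip through
#' [load_run_config()] reproduces the configuration exactly.
#'
#' @param config a [sim_config()].
#' @param path output path; the extension selects the format.
#' @param seed optional seed stored with the config.
#' @return the path, invisibly.
#' @export
save_run_config <- function(config, path, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  out <- list(
    n_agents = config$n_agents,
    space_size = config$space_size,
    threats_enabled = config$threats_enabled,
    pb_enabled = config$pb_enabled,
    max_pop = config$max_pop,
    behaviour = unclass(config$behaviour),
    demography = unclass(config$demography),
    central_institution = unclass(config$institutions),
    schedule = unclass(config$schedule)
  )
  if (!is.null(seed)) out$seed <- as.integer(seed)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  else yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' Write a results table to CSV
#'
#' Stable column order (sampled parameters first, then schedule, seed and
#' outcomes), header row, UTF-8, rows ordered by design index then
#' schedule.
#'
#' @param results a results table from [run_experiment_batch()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_results_table <- function(results, path) {
  if (is.null(results) || nrow(results) == 0)
    stop("results table is empty")
  outcome_cols <- c("schedule", "seed", "final_pop", "final_mean_rel",
                    "success", "pop_trend", "rel_trend", "pace_smf",
                    "pace_mf", "pace_f", "error", "design_index")
  par_cols <- setdiff(names(results), outcome_cols)
  ord <- results
  if (all(c("design_index", "schedule") %in% names(results)))
    ord <- results[order(results$design_index, results$schedule), ]
  utils::write.csv(ord[, c(par_cols, intersect(outcome_cols, names(results)))],
                   path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a trajectory (and its sampled series) to CSV
#'
#' @param traj a `trajectory`.
#' @param path output CSV path for the yearly series; the sampled series
#'   goes to the same name with suffix `_sampled`.
#' @return the path, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  spath <- sub("(\\.[^.]+)?$", "_sampled\\1", path)
  utils::write.csv(sampled_series(traj), spath, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
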