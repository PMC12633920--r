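# Latin-hypercube experiment driver: design generation over the standard
# sweep ranges, batch execution across reproduction/institution schedules,
# and enrichment of the results table with all trajectory classifications.

#' Parameter ranges of the standard sensitivity sweeps
#'
#' The named `(min, max)` ranges of the behavioural parameters varied in the
#' staged sensitivity analyses: the initial broad sweep, the narrowed sweep
#' (prosocial behaviour made cheap and easy to trigger, at least five
#' beneficiaries), the focused sweep (additionally high insecurity relief),
#' and the central-institution sweep (focused ranges with threats capped at
#' 0.3 and religiosity decay at 0.25, plus parochial prosociality and the
#' two institution parameters).
#'
#' @param stage one of `"broad"`, `"narrowed"`, `"focused"`, `"ci"`.
#' @return a data.frame with columns `parameter`, `min`, `max`.
#' @export
sweep_ranges <- function(stage = c("broad", "narrowed", "focused", "ci")) {
  stage <- match.arg(stage)
  base <- data.frame(
    parameter = c("pb_threshold", "pb_inc_rel_self", "pb_inc_rel_neigh",
                  "pb_dec_insec_self", "pb_dec_insec_neigh",
                  "pb_wellbeing_cost", "num_neigh_benefited", "threat_value",
                  "rel_dec_perc"),
    min = c(0.001, 0.1, 0.1, 0.1, 0.1, 0.001, 0, 0.001, 0.001),
    max = c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 10, 0.5, 0.5),
    stringsAsFactors = FALSE)
  set_range <- function(df, par, lo = NULL, hi = NULL) {
    i <- match(par, df$parameter)
    if (!is.null(lo)) df$min[i] <- lo
    if (!is.null(hi)) df$max[i] <- hi
    df
  }
  if (stage == "broad") return(base)
  df <- set_range(base, "pb_threshold", hi = 0.1)
  df <- set_range(df, "pb_wellbeing_cost", hi = 0.1)
  df <- set_range(df, "num_neigh_benefited", lo = 5)
  if (stage == "narrowed") return(df)
  df <- set_range(df, "pb_threshold", hi = 0.05)
  df <- set_range(df, "pb_wellbeing_cost", hi = 0.025)
  df <- set_range(df, "pb_dec_insec_self", lo = 0.25)
  df <- set_range(df, "pb_dec_insec_neigh", lo = 0.25)
  if (stage == "focused") return(df)
  df <- set_range(df, "threat_value", hi = 0.3)
  df <- set_range(df, "rel_dec_perc", hi = 0.25)
  rbind(df, data.frame(
    parameter = c("parochial_prosociality", "ci_wb_cost", "ci_benefit"),
    min = c(0.2, 0.001, 0.1),
    max = c(1.0, 0.050, 0.5),
    stringsAsFactors = FALSE))
}

#' Latin-hypercube design over parameter ranges
#'
#' Stratified space-filling design: for every parameter, exactly one of the
#' `n_samples` points falls in each of the `n_samples` equal-width strata of
#' its range. Parameters listed in `integer_params` are rounded to the
#' nearest integer after sampling.
#'
#' @param ranges a data.frame as returned by [sweep_ranges()] (columns
#'   `parameter`, `min`, `max`).
#' @param n_samples number of design points.
#' @param seed integer seed; identical seeds give identical designs.
#' @param integer_params parameter names rounded after sampling.
#' @return data.frame with one column per parameter and an attribute
#'   `ranges`.
#' @export
latin_hypercube_design <- function(ranges, n_samples, seed,
                                   integer_params = "num_neigh_benefited") {
  if (!all(c("parameter", "min", "max") %in% names(ranges)))
    stop("ranges must have columns parameter, min, max")
  if (any(ranges$min >= ranges$max))
    stop(sprintf("invalid range for '%s': min must be below max",
                 ranges$parameter[which(ranges$min >= ranges$max)[1]]))
  if (n_samples < 1) stop("n_samples must be at least 1")
  set.seed(as.integer(seed))
  u <- lhs::randomLHS(n_samples, nrow(ranges))
  m <- sweep(sweep(u, 2, ranges$max - ranges$min, "*"), 2, ranges$min, "+")
  colnames(m) <- ranges$parameter
  design <- as.data.frame(m)
  for (p in intersect(integer_params, names(design)))
    design[[p]] <- round(design[[p]])
  attr(design, "ranges") <- ranges
  attr(design, "seed") <- as.integer(seed)
  design
}

#' Full-factorial grid design
#'
#' Generic companion to [latin_hypercube_design()] for user-supplied level
#' sets: the cross product of the given levels, one column per parameter.
#'
#' @param levels named list, one numeric vector of levels per parameter.
#' @return data.frame with one row per combination.
#' @export
grid_design <- function(levels) {
  stopifnot(is.list(levels), length(levels) >= 1, !is.null(names(levels)))
  expand.grid(levels, KEEP.OUT.ATTRS = FALSE)
}

# apply one design row (+ schedule) on top of a base configuration
config_for_run <- function(base_config, row, schedule_timing,
                           ci_timing = NULL) {
  b <- base_config$behaviour
  i <- base_config$institutions
  bp <- unclass(b)
  for (nm in intersect(names(row), names(bp))) bp[[nm]] <- row[[nm]]
  bp$num_neigh_benefited <- as.integer(round(bp$num_neigh_benefited))
  class(bp) <- "behaviour_params"
  ip <- unclass(i)
  if ("ci_benefit" %in% names(row)) {
    ip$ci_benefit <- row[["ci_benefit"]]
    ip$ci_enabled <- TRUE
  }
  if ("ci_wb_cost" %in% names(row)) {
    ip$ci_wb_cost <- row[["ci_wb_cost"]]
    ip$ci_enabled <- TRUE
  }
  class(ip) <- "institution_params"
  sc <- unclass(base_config$schedule)
  sc$reproduction_timing <- schedule_timing
  if (!is.null(ci_timing)) sc$ci_timing <- ci_timing
  class(sc) <- "schedule_config"
  cfg <- base_config
  cfg$behaviour <- bp
  cfg$institutions <- ip
  cfg$schedule <- sc
  cfg
}

#' Run a batch of simulations over a design
#'
#' Executes one simulation per design row and schedule variant and returns
#' a results table carrying the sampled parameters, the schedule, the
#' per-run seed, the final population and mean religiosity, and the full
#' set of classifications: success, population trend, religiosity trend and
#' the nested decline-pace flags (set only for thriving societies with
#' declining religiosity).
#'
#' Per-run seeds are drawn reproducibly from `seed`; the same design row
#' shares its seed across schedules (common random numbers), so schedule
#' contrasts are paired. With `cores > 1` rows are distributed over forked
#' workers with results identical to serial execution.
#'
#' @param design a design data.frame (see [latin_hypercube_design()]).
#' @param base_config the configuration the sampled parameters overwrite;
#'   defaults to the calibrated reference demography with threats and PB on.
#' @param schedules character vector of reproduction timings to run.
#' @param ci_timing optional central-institution timing applied to all runs.
#' @param seed integer master seed.
#' @param cores forked workers (1 = serial).
#' @param progress print a dot every 50 design rows.
#' @return a `data.frame` with one row per (design row x schedule).
#' @export
run_experiment_batch <- function(design,
                                 base_config = sim_config(),
                                 schedules = c("before_pb", "random",
                                               "after_pb"),
                                 ci_timing = NULL,
                                 seed = 1L, cores = 1L, progress = FALSE) {
  stopifnot(nrow(design) >= 1)
  set.seed(as.integer(seed))
  run_seeds <- sample.int(.Machine$integer.max - 1L, nrow(design))
  horizon <- base_config$schedule$horizon

  one_row <- function(i) {
    row <- as.list(design[i, , drop = FALSE])
    out <- lapply(schedules, function(sch) {
      res <- tryCatch({
        cfg <- config_for_run(base_config, row, sch, ci_timing)
        traj <- run_simulation(cfg, run_seeds[i])
        s <- sampled_series(traj)
        final_pop <- s$pop[nrow(s)]
        final_rel <- s$mean_rel[nrow(s)]
        pop_trend <- classify_population_trajectory(traj)
        rel_trend <- classify_religiosity_trajectory(traj)
        tsdr <- pop_trend == "thriving" && rel_trend == "declining"
        pace <- if (tsdr) pace_category(rel_trend, final_rel)
                else c(smf = FALSE, mf = FALSE, f = FALSE)
        data.frame(row, schedule = sch, seed = run_seeds[i],
                   final_pop = final_pop, final_mean_rel = final_rel,
                   success = is_successful(traj),
                   pop_trend = pop_trend, rel_trend = rel_trend,
                   pace_smf = unname(pace["smf"]), pace_mf = unname(pace["mf"]),
                   pace_f = unname(pace["f"]), error = NA_character_,
                   stringsAsFactors = FALSE)
      }, error = function(e) {
        data.frame(row, schedule = sch, seed = run_seeds[i],
                   final_pop = NA_real_, final_mean_rel = NA_real_,
                   success = NA, pop_trend = NA_character_,
                   rel_trend = NA_character_, pace_smf = NA, pace_mf = NA,
                   pace_f = NA, error = conditionMessage(e),
                   stringsAsFactors = FALSE)
      })
      res
    })
    do.call(rbind, out)
  }

  idx <- seq_len(nrow(design))
  if (cores > 1L) {
    chunks <- parallel::mclapply(idx, one_row, mc.cores = cores,
                                 mc.preschedule = TRUE)
  } else {
    chunks <- vector("list", length(idx))
    for (i in idx) {
      chunks[[i]] <- one_row(i)
      if (progress && i %% 50 == 0) cat(".")
    }
    if (progress) cat("\n")
  }
  res <- do.call(rbind, chunks)
  res$design_index <- rep(idx, each = length(schedules))
  rownames(res) <- NULL
  attr(res, "ranges") <- attr(design, "ranges")
  attr(res, "horizon") <- horizon
  res
}

#' Share of successful runs per schedule
#'
#' @param results a results table from [run_experiment_batch()].
#' @return named numeric vector of success percentages (0-100) by schedule.
#' @export
success_rates <- function(results) {
  sapply(split(results$success, results$schedule),
         function(v) 100 * mean(v, na.rm = TRUE))
}

#' Cross-tabulated percentages of a classification column per schedule
#'
#' @param results a results table.
#' @param column classification column, e.g. `"pop_trend"` or
#'   `"rel_trend"`.
#' @return a percentage matrix, categories x schedules.
#' @export
category_shares <- function(results, column = "pop_trend") {
  tab <- table(results[[column]], results$schedule)
  100 * prop.table(tab, margin = 2)
}
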