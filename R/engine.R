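# Yearly scheduler and whole-run driver. The heavy lifting happens in the
# compiled engine (src/engine.cpp); the R functions here expose the same
# stages individually so each can be exercised and audited on its own. All
# stage functions consume and return a `society`, advancing the engine RNG
# state carried inside it, so composing them in the documented order is
# bit-identical to cpp_run_years().

as_society <- function(lst) {
  lst <- lst[c("id", "age", "female", "married", "partner", "religiosity",
               "wellbeing", "insecurity", "sensitivity", "anxiety", "x", "y",
               "year", "next_id", "space_size", "rng_state")]
  class(lst) <- "society"
  lst
}

#' Apply one year of external threats
#'
#' Adds `threat_value` to every agent's insecurity (clamped at 1) and
#' recomputes anxiety. The yearly scheduler calls this automatically from
#' `threat_start_year` on; the exported form lets a given value be applied
#' directly.
#'
#' @param society a `society`.
#' @param threat_value nonnegative insecurity increment.
#' @return the updated society.
#' @export
apply_threats <- function(society, threat_value) {
  if (!is.numeric(threat_value) || length(threat_value) != 1 ||
      is.na(threat_value) || threat_value < 0)
    stop("threat_value must be a single nonnegative number")
  as_society(cpp_apply_threats(society, threat_value))
}

#' Marriage formation stage
#'
#' Pairs single agents strictly older than the minimum marriage age with a
#' uniformly chosen unmatched opposite-gender candidate whose age differs by
#' at most `marriage_age_diff`, visiting agents in a freshly shuffled order.
#'
#' @param society a `society`.
#' @param config a [sim_config()].
#' @return the updated society.
#' @export
form_marriages <- function(society, config) {
  as_society(cpp_form_marriages(society, engine_params(config)))
}

#' Reproduction stage
#'
#' Gives every married female of reproductive age one birth opportunity with
#' probability [reproduction_probability()]; both parents pay `rep_cost` of
#' their own wellbeing, the offspring starts with the summed losses and
#' copies religiosity, insecurity and sensitivity from one parent chosen at
#' random.
#'
#' @param society a `society`.
#' @param config a [sim_config()].
#' @return the updated society, with attribute `births`.
#' @export
reproduction_stage <- function(society, config) {
  out <- cpp_reproduction(society, engine_params(config))
  soc <- as_society(out)
  attr(soc, "births") <- out$births
  soc
}

#' Prosocial-behaviour stage
#'
#' Visits agents in a freshly shuffled order; each recomputes anxiety and, if
#' of age and triggered ([pb_trigger()]), performs one prosocial act: the
#' performer pays the wellbeing cost and insecurity/religiosity effects are
#' applied to itself and to up to `num_neigh_benefited` beneficiaries drawn
#' uniformly from the eligible neighbours (see [eligible_beneficiaries()]).
#'
#' @param society a `society`.
#' @param config a [sim_config()].
#' @return the updated society, with attribute `pb_count`.
#' @export
pb_stage <- function(society, config) {
  out <- cpp_pb_stage(society, engine_params(config))
  soc <- as_society(out)
  attr(soc, "pb_count") <- out$pb_count
  soc
}

#' Central-institution stage
#'
#' From `ci_start_year` on, every living agent receives the yearly
#' insecurity reduction `ci_benefit` (floored at 0) and every agent strictly
#' older than `ci_min_tax_age` pays `ci_wb_cost` wellbeing (floored at 0);
#' anxiety is recomputed. A no-op before the start year or when the
#' institution is disabled.
#'
#' @param society a `society`.
#' @param params an [institution_params()] block.
#' @param year the simulation year being executed (defaults to the society's
#'   next year).
#' @param ci_start_year first year of effect.
#' @return the updated society.
#' @export
apply_central_institution <- function(society, params,
                                      year = society$year + 1L,
                                      ci_start_year = 200L) {
  stopifnot(inherits(params, "institution_params"))
  if (!params$ci_enabled || year < ci_start_year) return(society)
  cfg <- sim_config(institutions = params)
  as_society(cpp_apply_ci(society, engine_params(cfg)))
}

#' Wellbeing update stage (age-linked then insecurity-linked deltas)
#'
#' @param society a `society`.
#' @param config a [sim_config()].
#' @return the updated society.
#' @export
wellbeing_stage <- function(society, config) {
  as_society(cpp_wb_update(society, engine_params(config)))
}

#' Religiosity decay stage
#'
#' @param society a `society`.
#' @param config a [sim_config()].
#' @return the updated society.
#' @export
decay_stage <- function(society, config) {
  as_society(cpp_decay_religiosity(society, engine_params(config)))
}

#' Mortality stage
#'
#' Each agent dies independently with [death_probability()] of its wellbeing;
#' the dead are removed and surviving spouses become single.
#'
#' @param society a `society`.
#' @param config a [sim_config()].
#' @return the updated society, with attribute `deaths`.
#' @export
apply_mortality <- function(society, config) {
  out <- cpp_apply_mortality(society, engine_params(config))
  soc <- as_society(out)
  attr(soc, "deaths") <- out$deaths
  soc
}

#' Advance a society by one year
#'
#' Executes the full yearly cycle: marriage, threats (from
#' `threat_start_year`), central institution (if scheduled before PB),
#' reproduction (if scheduled before PB; under `"random"` timing one fair
#' coin per year decides), the prosocial-behaviour sweep, the remaining
#' institution/reproduction slot, the age- and insecurity-linked wellbeing
#' deltas, religiosity decay, mortality, and ageing.
#'
#' @param society a `society`.
#' @param config a [sim_config()].
#' @return the updated society with attributes `births`, `deaths`,
#'   `pb_count`.
#' @export
step_year <- function(society, config) {
  out <- cpp_run_years(society, engine_params(config), 1L,
                       return_society = TRUE)
  soc <- as_society(out$society)
  tr <- out$trajectory
  attr(soc, "births") <- tr[1, "births"]
  attr(soc, "deaths") <- tr[1, "deaths"]
  attr(soc, "pb_count") <- tr[1, "pb_count"]
  soc
}

#' Run a full simulation
#'
#' Initialises a society from `config` and `seed`, advances it `horizon`
#' years, and returns the trajectory: one row per year (year 0 is the
#' initial state) with population size, mean religiosity, insecurity and
#' wellbeing, and the year's births, deaths and prosocial-act count, plus
#' the coarse series sampled every `record_interval` years used by all
#' analytics. On extinction the remaining years are recorded with
#' population 0.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; identical (config, seed) pairs give identical
#'   trajectories.
#' @return a `trajectory` object (a data.frame with attributes `sampled`,
#'   `capped`, `final_pop`, `seed`).
#' @export
run_simulation <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  society <- initialize_society(config, seed)
  horizon <- config$schedule$horizon
  out <- cpp_run_years(society, engine_params(config), horizon,
                       return_society = FALSE)
  yearly <- as.data.frame(out$trajectory)
  yearly <- rbind(society_summary(society), yearly)
  new_trajectory(yearly, config$schedule$record_interval,
                 capped = out$capped, final_pop = out$final_pop, seed = seed)
}

new_trajectory <- function(yearly, record_interval, capped = FALSE,
                           final_pop = NULL, seed = NULL) {
  rownames(yearly) <- NULL
  sampled <- yearly[yearly$year %% record_interval == 0,
                    c("year", "pop", "mean_rel")]
  rownames(sampled) <- NULL
  structure(yearly,
            sampled = sampled,
            record_interval = record_interval,
            capped = capped,
            final_pop = if (is.null(final_pop)) yearly$pop[nrow(yearly)]
                        else final_pop,
            seed = seed,
            class = c("trajectory", "data.frame"))
}

#' Coarse sampled series of a trajectory
#'
#' @param traj a `trajectory`.
#' @return data.frame with columns `year`, `pop`, `mean_rel`, one row per
#'   `record_interval` years.
#' @export
sampled_series <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  attr(traj, "sampled")
}

#' @export
print.trajectory <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf(
    "<trajectory> %d years, final population %d, final mean religiosity %s\n",
    x$year[n], as.integer(x$pop[n]),
    ifelse(is.na(x$mean_rel[n]), "NA", sprintf("%.3f", x$mean_rel[n]))))
  invisible(x)
}

#' Plot a trajectory
#'
#' Two stacked base-graphics panels: population size and mean religiosity
#' against year.
#'
#' @param x a `trajectory`.
#' @param ... passed to `plot()`.
#' @importFrom graphics par lines abline
#' @export
plot.trajectory <- function(x, ...) {
  op <- par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(par(op))
  plot(x$year, x$pop, type = "l", xlab = "year", ylab = "population", ...)
  plot(x$year, x$mean_rel, type = "l", xlab = "year",
       ylab = "mean religiosity", ylim = c(0, 1), ...)
  invisible(x)
}
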