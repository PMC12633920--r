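#' @useDynLib prosoceq, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor.test pt rnorm runif setNames median
#' @importFrom utils modifyList read.csv write.csv
#' @importFrom parallel mclapply
NULL

.check_num <- function(value, name, lo = -Inf, hi = Inf, len = 1L,
                       integer = FALSE) {
  if (!is.numeric(value) || length(value) != len || anyNA(value))
    stop(sprintf("config field '%s' must be numeric of length %d", name, len),
         call. = FALSE)
  if (any(value < lo) || any(value > hi))
    stop(sprintf("config field '%s' must lie in [%s, %s]", name,
                 format(lo), format(hi)), call. = FALSE)
  if (integer && any(value != round(value)))
    stop(sprintf("config field '%s' must be an integer", name), call. = FALSE)
  invisible(value)
}

#' Behavioural parameters: prosocial behaviour, threats and religiosity decay
#'
#' Bundles every tunable of the threat / anxiety / prosocial-behaviour (PB)
#' machinery. PB is triggered when `anxiety * religiosity` strictly exceeds
#' `pb_threshold`; a performing agent pays `pb_wellbeing_cost` of wellbeing,
#' loses `pb_dec_insec_self` insecurity, and (while of socialisation age)
#' gains `pb_inc_rel_self` religiosity. Up to `num_neigh_benefited`
#' neighbours within `radius_local_area` whose religiosity exceeds the
#' performer's minus `parochial_prosociality` are drawn uniformly; each loses
#' `pb_dec_insec_neigh` insecurity and, if young enough, gains
#' `pb_inc_rel_neigh` religiosity.
#'
#' @param pb_threshold strict trigger threshold on anxiety x religiosity.
#' @param pb_inc_rel_self,pb_inc_rel_neigh additive religiosity gains
#'   (performer / beneficiary), applied only up to `socialisation_max_age`.
#' @param pb_dec_insec_self,pb_dec_insec_neigh additive insecurity relief.
#' @param pb_wellbeing_cost wellbeing paid by the performer per act.
#' @param num_neigh_benefited maximum number of beneficiaries per act.
#' @param threat_value yearly insecurity increment from external threats.
#' @param threat_mode `"constant"` applies `threat_value` every year;
#'   `"stochastic"` draws each year's value from Uniform(0, 2 * threat_value)
#'   (same mean).
#' @param rel_dec_perc yearly religiosity decay rate for agents still in the
#'   decay window (under 26 by default).
#' @param rel_dec_mode `"multiplicative"` (religiosity scaled by
#'   `1 - rel_dec_perc`) or `"additive"`.
#' @param rel_dec_min_age lower bound of the decay window (0 applies decay to
#'   everyone under 26; 12 restricts it to the socialisation years).
#' @param rel_dec_from_threat_start if `TRUE` (default) the yearly decay,
#'   like threats and prosocial behaviour, only operates from the schedule's
#'   `threat_start_year` on, so the stabilisation era has no religiosity
#'   dynamics; `FALSE` applies decay from year 0.
#' @param parochial_prosociality tolerance of the parochial rule; 1 disables
#'   parochialism entirely.
#' @param radius_local_area neighbourhood radius in space units.
#' @param pb_min_age minimum age to perform PB.
#' @param socialisation_max_age last age at which religiosity still responds
#'   to performing or receiving PB.
#' @return a `behaviour_params` list.
#' @export
behaviour_params <- function(pb_threshold = 0.025,
                             pb_inc_rel_self = 0.3,
                             pb_inc_rel_neigh = 0.3,
                             pb_dec_insec_self = 0.375,
                             pb_dec_insec_neigh = 0.375,
                             pb_wellbeing_cost = 0.013,
                             num_neigh_benefited = 7L,
                             threat_value = 0.15,
                             threat_mode = c("constant", "stochastic"),
                             rel_dec_perc = 0.1,
                             rel_dec_mode = c("multiplicative", "additive"),
                             rel_dec_min_age = 0L,
                             rel_dec_from_threat_start = TRUE,
                             parochial_prosociality = 1,
                             radius_local_area = 50,
                             pb_min_age = 12L,
                             socialisation_max_age = 25L) {
  threat_mode <- match.arg(threat_mode)
  rel_dec_mode <- match.arg(rel_dec_mode)
  .check_num(pb_threshold, "pb_threshold", 0, 1)
  .check_num(pb_inc_rel_self, "pb_inc_rel_self", 0, 1)
  .check_num(pb_inc_rel_neigh, "pb_inc_rel_neigh", 0, 1)
  .check_num(pb_dec_insec_self, "pb_dec_insec_self", 0, 1)
  .check_num(pb_dec_insec_neigh, "pb_dec_insec_neigh", 0, 1)
  .check_num(pb_wellbeing_cost, "pb_wellbeing_cost", 0, 1)
  .check_num(num_neigh_benefited, "num_neigh_benefited", 0, Inf,
             integer = TRUE)
  .check_num(threat_value, "threat_value", 0, 1)
  .check_num(rel_dec_perc, "rel_dec_perc", 0, 1)
  .check_num(rel_dec_min_age, "rel_dec_min_age", 0, 26, integer = TRUE)
  .check_num(parochial_prosociality, "parochial_prosociality", 0, 1)
  .check_num(radius_local_area, "radius_local_area", 0, Inf)
  .check_num(pb_min_age, "pb_min_age", 0, 200, integer = TRUE)
  .check_num(socialisation_max_age, "socialisation_max_age", 0, 200,
             integer = TRUE)
  structure(list(
    pb_threshold = pb_threshold,
    pb_inc_rel_self = pb_inc_rel_self,
    pb_inc_rel_neigh = pb_inc_rel_neigh,
    pb_dec_insec_self = pb_dec_insec_self,
    pb_dec_insec_neigh = pb_dec_insec_neigh,
    pb_wellbeing_cost = pb_wellbeing_cost,
    num_neigh_benefited = as.integer(round(num_neigh_benefited)),
    threat_value = threat_value,
    threat_mode = threat_mode,
    rel_dec_perc = rel_dec_perc,
    rel_dec_mode = rel_dec_mode,
    rel_dec_min_age = as.integer(rel_dec_min_age),
    rel_dec_from_threat_start = isTRUE(rel_dec_from_threat_start),
    parochial_prosociality = parochial_prosociality,
    radius_local_area = radius_local_area,
    pb_min_age = as.integer(pb_min_age),
    socialisation_max_age = as.integer(socialisation_max_age)
  ), class = "behaviour_params")
}

#' Demographic parameters: wellbeing, mortality, marriage and reproduction
#'
#' The wellbeing / mortality / marriage / reproduction block. Most arguments
#' default to the package's calibrated reference profile (see
#' [calibrated_profile()]); the fixed constants (`importance_*`,
#' `wb_insec_threshold`, `wb_max_dec`) keep their canonical values.
#'
#' `mortality_curve` and `init_wb_curve` are polynomial coefficient vectors
#' (intercept first) mapping wellbeing to yearly death probability and age to
#' initial wellbeing respectively; evaluations are clamped into \[0, 1\].
#'
#' @param rep_cost fraction of each parent's wellbeing spent per birth.
#' @param rep_mid_threshold sigmoid midpoint `a`: reproduction probability is
#'   0.5 when the weighted wellbeing/insecurity average equals it.
#' @param rep_curve_shape sigmoid steepness `b`.
#' @param importance_insec,importance_wb weights of insecurity and wellbeing
#'   in the reproduction decision.
#' @param wb_age_threshold age at which the yearly age-linked wellbeing delta
#'   switches from the gain to the loss regime.
#' @param wb_intercept_C intercept `C` of the age-linked delta (delta is `C`
#'   exactly at the threshold and `-3C` at age 100).
#' @param wb_exp_gain,wb_exp_loss shape exponents of the two regimes.
#' @param wb_insec_threshold insecurity level at which the insecurity-linked
#'   wellbeing delta is zero.
#' @param wb_max_inc maximum yearly wellbeing gain (at insecurity 0).
#' @param wb_max_dec maximum yearly wellbeing loss (at insecurity 1).
#' @param wb_insec_printed_form if `TRUE`, use the gain branch with a slope
#'   that grows with insecurity instead of the endpoint-consistent line; kept
#'   as a robustness flag, see the methods vignette.
#' @param marriage_age_diff maximum age difference between spouses, years.
#' @param marriage_min_age agents must be strictly older than this to marry.
#' @param repro_age_min,repro_age_max female reproductive age window.
#' @param mortality_curve polynomial coefficients, wellbeing -> death
#'   probability.
#' @param init_wb_curve polynomial coefficients, age -> initial wellbeing.
#' @param profile a named list used to fill unset calibrated arguments;
#'   defaults to the shipped calibrated profile.
#' @return a `demography_params` list.
#' @export
demography_params <- function(rep_cost = NULL,
                              rep_mid_threshold = NULL,
                              rep_curve_shape = NULL,
                              importance_insec = 0.5,
                              importance_wb = 1,
                              wb_age_threshold = NULL,
                              wb_intercept_C = NULL,
                              wb_exp_gain = NULL,
                              wb_exp_loss = NULL,
                              wb_insec_threshold = 0.1,
                              wb_max_inc = NULL,
                              wb_max_dec = 0.25,
                              wb_insec_printed_form = FALSE,
                              marriage_age_diff = NULL,
                              marriage_min_age = 15L,
                              repro_age_min = 15L,
                              repro_age_max = 49L,
                              mortality_curve = default_mortality_curve(),
                              init_wb_curve = default_init_wb_curve(),
                              profile = calibrated_profile()) {
  fill <- function(val, nm) {
    if (!is.null(val)) return(val)
    if (!is.null(profile[[nm]])) return(profile[[nm]])
    stop(sprintf("config field '%s' is unset and absent from the profile", nm),
         call. = FALSE)
  }
  rep_cost <- fill(rep_cost, "rep_cost")
  rep_mid_threshold <- fill(rep_mid_threshold, "rep_mid_threshold")
  rep_curve_shape <- fill(rep_curve_shape, "rep_curve_shape")
  wb_age_threshold <- fill(wb_age_threshold, "wb_age_threshold")
  wb_intercept_C <- fill(wb_intercept_C, "wb_intercept_C")
  wb_exp_gain <- fill(wb_exp_gain, "wb_exp_gain")
  wb_exp_loss <- fill(wb_exp_loss, "wb_exp_loss")
  wb_max_inc <- fill(wb_max_inc, "wb_max_inc")
  marriage_age_diff <- fill(marriage_age_diff, "marriage_age_diff")

  .check_num(rep_cost, "rep_cost", 0, 1)
  .check_num(rep_mid_threshold, "rep_mid_threshold", 0, 1)
  .check_num(rep_curve_shape, "rep_curve_shape", 0, Inf)
  .check_num(importance_insec, "importance_insec", 0, Inf)
  .check_num(importance_wb, "importance_wb", 0, Inf)
  if (importance_insec + importance_wb <= 0)
    stop("config field 'importance_wb': weights must not both be zero",
         call. = FALSE)
  .check_num(wb_age_threshold, "wb_age_threshold", 0, 99)
  .check_num(wb_intercept_C, "wb_intercept_C", 0, 1)
  .check_num(wb_exp_gain, "wb_exp_gain", 0, Inf)
  .check_num(wb_exp_loss, "wb_exp_loss", 0, Inf)
  if (wb_insec_threshold <= 0 || wb_insec_threshold >= 1)
    stop("config field 'wb_insec_threshold' must lie strictly in (0, 1)",
         call. = FALSE)
  .check_num(wb_max_inc, "wb_max_inc", 0, 1)
  .check_num(wb_max_dec, "wb_max_dec", 0, 1)
  .check_num(marriage_age_diff, "marriage_age_diff", 0, Inf)
  .check_num(marriage_min_age, "marriage_min_age", 0, 200, integer = TRUE)
  .check_num(repro_age_min, "repro_age_min", 0, 200, integer = TRUE)
  .check_num(repro_age_max, "repro_age_max", 0, 200, integer = TRUE)
  if (!is.numeric(mortality_curve) || length(mortality_curve) < 1)
    stop("config field 'mortality_curve' must be a numeric coefficient vector",
         call. = FALSE)
  if (!is.numeric(init_wb_curve) || length(init_wb_curve) < 1)
    stop("config field 'init_wb_curve' must be a numeric coefficient vector",
         call. = FALSE)
  structure(list(
    rep_cost = rep_cost,
    rep_mid_threshold = rep_mid_threshold,
    rep_curve_shape = rep_curve_shape,
    importance_insec = importance_insec,
    importance_wb = importance_wb,
    wb_age_threshold = wb_age_threshold,
    wb_intercept_C = wb_intercept_C,
    wb_exp_gain = wb_exp_gain,
    wb_exp_loss = wb_exp_loss,
    wb_insec_threshold = wb_insec_threshold,
    wb_max_inc = wb_max_inc,
    wb_max_dec = wb_max_dec,
    wb_insec_printed_form = isTRUE(wb_insec_printed_form),
    marriage_age_diff = marriage_age_diff,
    marriage_min_age = as.integer(marriage_min_age),
    repro_age_min = as.integer(repro_age_min),
    repro_age_max = as.integer(repro_age_max),
    mortality_curve = as.numeric(mortality_curve),
    init_wb_curve = as.numeric(init_wb_curve)
  ), class = "demography_params")
}

#' Central-institution parameters
#'
#' A central institution (CI) grants every living agent a yearly insecurity
#' reduction of `ci_benefit`, financed by a yearly wellbeing cost
#' `ci_wb_cost` paid by every agent strictly older than `ci_min_tax_age`.
#' The effect starts at the schedule's `ci_start_year`.
#'
#' @param ci_enabled logical, activate the institution.
#' @param ci_benefit yearly insecurity reduction for all agents.
#' @param ci_wb_cost yearly wellbeing cost for taxed adults.
#' @param ci_min_tax_age agents strictly above this age pay the cost.
#' @return an `institution_params` list.
#' @export
institution_params <- function(ci_enabled = FALSE, ci_benefit = 0.3,
                               ci_wb_cost = 0.025, ci_min_tax_age = 18L) {
  .check_num(ci_benefit, "ci_benefit", 0, Inf)
  .check_num(ci_wb_cost, "ci_wb_cost", 0, Inf)
  .check_num(ci_min_tax_age, "ci_min_tax_age", 0, 200, integer = TRUE)
  structure(list(
    ci_enabled = isTRUE(ci_enabled),
    ci_benefit = ci_benefit,
    ci_wb_cost = ci_wb_cost,
    ci_min_tax_age = as.integer(ci_min_tax_age)
  ), class = "institution_params")
}

#' Schedule of the yearly cycle
#'
#' @param reproduction_timing when the reproduction opportunity falls
#'   relative to the prosocial-behaviour stage: `"before_pb"`, `"after_pb"`,
#'   or `"random"` (one fair coin per year, not per agent).
#' @param ci_timing central-institution effect before or after PB.
#' @param threat_start_year first year in which threats (and hence anxiety
#'   and PB) act; the society runs threat-free until then. Defaults to year
#'   100, truncated to the horizon.
#' @param ci_start_year first year of central-institution effects; defaults
#'   to year 200, truncated to the horizon.
#' @param horizon total simulated years.
#' @param record_interval sampling interval of the coarse series; must
#'   divide the horizon.
#' @return a `schedule_config` list.
#' @export
schedule_config <- function(reproduction_timing = c("before_pb", "after_pb",
                                                    "random"),
                            ci_timing = c("after_pb", "before_pb"),
                            threat_start_year = NULL,
                            ci_start_year = NULL,
                            horizon = 600L,
                            record_interval = 25L) {
  reproduction_timing <- match.arg(reproduction_timing)
  ci_timing <- match.arg(ci_timing)
  .check_num(horizon, "horizon", 1, Inf, integer = TRUE)
  if (is.null(threat_start_year)) threat_start_year <- min(100L, horizon)
  if (is.null(ci_start_year))
    ci_start_year <- min(200L, max(horizon, threat_start_year))
  .check_num(threat_start_year, "threat_start_year", 0, Inf, integer = TRUE)
  .check_num(ci_start_year, "ci_start_year", 0, Inf, integer = TRUE)
  .check_num(horizon, "horizon", 1, Inf, integer = TRUE)
  .check_num(record_interval, "record_interval", 1, Inf, integer = TRUE)
  if (threat_start_year > ci_start_year)
    stop("config field 'threat_start_year' must not exceed 'ci_start_year'",
         call. = FALSE)
  if (ci_start_year > horizon)
    stop("config field 'ci_start_year' must not exceed 'horizon'",
         call. = FALSE)
  if (horizon %% record_interval != 0)
    stop("config field 'record_interval' must divide 'horizon'",
         call. = FALSE)
  structure(list(
    reproduction_timing = reproduction_timing,
    ci_timing = ci_timing,
    threat_start_year = as.integer(threat_start_year),
    ci_start_year = as.integer(ci_start_year),
    horizon = as.integer(horizon),
    record_interval = as.integer(record_interval)
  ), class = "schedule_config")
}

#' Full simulation configuration
#'
#' Assembles the behaviour, demography, institution and schedule blocks into
#' one validated bundle consumed by [initialize_society()] and
#' [run_simulation()].
#'
#' @param n_agents initial population size.
#' @param space_size side length of the square habitat (the default 500 makes
#'   the habitat diameter ten times the neighbourhood radius).
#' @param behaviour,demography,institutions,schedule parameter blocks; see
#'   [behaviour_params()], [demography_params()], [institution_params()],
#'   [schedule_config()].
#' @param threats_enabled master switch for yearly threats.
#' @param pb_enabled master switch for the prosocial-behaviour stage.
#' @param max_pop runtime cap: a run whose population exceeds this value
#'   halts, pads the remaining record with its last summary values and is
#'   flagged `capped` (such runs classify as thriving by convention); 0
#'   disables the cap.
#' @return a `sim_config` object.
#' @export
sim_config <- function(n_agents = 1000L, space_size = 500,
                       behaviour = behaviour_params(),
                       demography = demography_params(),
                       institutions = institution_params(),
                       schedule = schedule_config(),
                       threats_enabled = TRUE,
                       pb_enabled = TRUE,
                       max_pop = 2e4) {
  .check_num(n_agents, "n_agents", 1, Inf, integer = TRUE)
  .check_num(space_size, "space_size", 1e-9, Inf)
  .check_num(max_pop, "max_pop", 0, Inf)
  stopifnot(inherits(behaviour, "behaviour_params"),
            inherits(demography, "demography_params"),
            inherits(institutions, "institution_params"),
            inherits(schedule, "schedule_config"))
  structure(list(
    n_agents = as.integer(n_agents),
    space_size = space_size,
    behaviour = behaviour,
    demography = demography,
    institutions = institutions,
    schedule = schedule,
    threats_enabled = isTRUE(threats_enabled),
    pb_enabled = isTRUE(pb_enabled),
    max_pop = max_pop
  ), class = "sim_config")
}

#' Reference-model configuration (threats and prosocial behaviour off)
#'
#' Convenience wrapper producing the baseline used for calibration and as
#' the comparison standard: same demography, but no threats and no prosocial
#' behaviour, so insecurity stays at zero and only the demographic processes
#' act.
#'
#' @param demography a `demography_params` block (defaults to the calibrated
#'   profile).
#' @param horizon simulated years.
#' @param ... forwarded to [sim_config()].
#' @return a `sim_config` object.
#' @export
reference_config <- function(demography = demography_params(),
                             horizon = 600L, ...) {
  sim_config(demography = demography,
             schedule = schedule_config(horizon = horizon,
                                        record_interval = gcd_interval(horizon)),
             threats_enabled = FALSE, pb_enabled = FALSE, ...)
}

# largest of the standard sampling intervals that divides the horizon
gcd_interval <- function(horizon) {
  for (iv in c(25L, 10L, 5L, 1L)) if (horizon %% iv == 0L) return(iv)
  1L
}

# Flatten a sim_config into the scalar list consumed by the C++ engine.
engine_params <- function(config) {
  b <- config$behaviour; d <- config$demography
  i <- config$institutions; s <- config$schedule
  list(
    pb_enabled = as.numeric(config$pb_enabled),
    threats_enabled = as.numeric(config$threats_enabled),
    threat_stochastic = as.numeric(b$threat_mode == "stochastic"),
    ci_enabled = as.numeric(i$ci_enabled),
    rel_dec_additive = as.numeric(b$rel_dec_mode == "additive"),
    rel_dec_gated = as.numeric(b$rel_dec_from_threat_start),
    wb_insec_printed = as.numeric(d$wb_insec_printed_form),
    pb_threshold = b$pb_threshold,
    pb_inc_rel_self = b$pb_inc_rel_self,
    pb_inc_rel_neigh = b$pb_inc_rel_neigh,
    pb_dec_insec_self = b$pb_dec_insec_self,
    pb_dec_insec_neigh = b$pb_dec_insec_neigh,
    pb_wellbeing_cost = b$pb_wellbeing_cost,
    num_neigh_benefited = b$num_neigh_benefited,
    threat_value = b$threat_value,
    rel_dec_perc = b$rel_dec_perc,
    parochial_prosociality = b$parochial_prosociality,
    radius_local_area = b$radius_local_area,
    pb_min_age = b$pb_min_age,
    socialisation_max_age = b$socialisation_max_age,
    rel_dec_min_age = b$rel_dec_min_age,
    rep_cost = d$rep_cost,
    rep_mid_threshold = d$rep_mid_threshold,
    rep_curve_shape = d$rep_curve_shape,
    importance_insec = d$importance_insec,
    importance_wb = d$importance_wb,
    wb_age_threshold = d$wb_age_threshold,
    wb_intercept_C = d$wb_intercept_C,
    wb_exp_gain = d$wb_exp_gain,
    wb_exp_loss = d$wb_exp_loss,
    wb_insec_threshold = d$wb_insec_threshold,
    wb_max_inc = d$wb_max_inc,
    wb_max_dec = d$wb_max_dec,
    marriage_age_diff = d$marriage_age_diff,
    marriage_min_age = d$marriage_min_age,
    repro_min_age = d$repro_age_min,
    repro_max_age = d$repro_age_max,
    mortality_curve = d$mortality_curve,
    ci_benefit = i$ci_benefit,
    ci_wb_cost = i$ci_wb_cost,
    ci_min_tax_age = i$ci_min_tax_age,
    ci_start_year = s$ci_start_year,
    rep_timing = match(s$reproduction_timing,
                       c("before_pb", "after_pb", "random")) - 1L,
    ci_timing = match(s$ci_timing, c("before_pb", "after_pb")) - 1L,
    threat_start_year = s$threat_start_year,
    horizon = s$horizon,
    record_interval = s$record_interval,
    space_size = config$space_size,
    max_pop = config$max_pop
  )
}

#' Default mortality curve: wellbeing to yearly death probability
#'
#' Polynomial coefficients (intercept first) of the shipped default curve
#' `p(w) = 0.95 (1 - w)^4`: death is near certain at wellbeing 0 and nearly
#' impossible at wellbeing 1, falling smoothly and monotonically in between,
#' mirroring a mid-century life-table silhouette with wellbeing standing in
#' for age.
#'
#' @return numeric coefficient vector.
#' @export
default_mortality_curve <- function() {
  0.95 * c(1, -4, 6, -4, 1)
}

#' Default initial-wellbeing curve: age to wellbeing at initialisation
#'
#' Coefficients of `wb(a) = 0.95 (1 - (a/105)^3)`: high and nearly flat
#' through childhood and adulthood, declining at old ages.
#'
#' @return numeric coefficient vector.
#' @export
default_init_wb_curve <- function() {
  c(0.95, 0, 0, -0.95 / 105^3)
}
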