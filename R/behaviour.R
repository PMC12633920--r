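#' Prosocial-behaviour trigger rule
#'
#' An agent performs a prosocial act in a given year when the multiplicative
#' interaction of its anxiety and religiosity strictly exceeds the trigger
#' threshold. Vectorised over agents.
#'
#' @param anxiety,religiosity numeric vectors in \[0, 1\].
#' @param pb_threshold positive trigger threshold.
#' @return logical vector, `TRUE` where `anxiety * religiosity >
#'   pb_threshold`.
#' @export
#' @examples
#' pb_trigger(0.4, 0.2, 0.05)  # TRUE: 0.08 > 0.05
pb_trigger <- function(anxiety, religiosity, pb_threshold) {
  anxiety * religiosity > pb_threshold
}

#' Eligible beneficiaries of a prosocial act
#'
#' The agents a performer may benefit: every other living agent within the
#' neighbourhood radius whose religiosity strictly exceeds the performer's
#' religiosity minus the parochial-prosociality tolerance. With the
#' tolerance at 1 the religiosity condition never binds and parochialism is
#' effectively disabled.
#'
#' @param performer_id id of the performing agent.
#' @param society a `society`.
#' @param params a [behaviour_params()] block.
#' @return integer vector of eligible agent ids (possibly empty).
#' @export
eligible_beneficiaries <- function(performer_id, society, params) {
  i <- match(performer_id, society$id)
  if (is.na(i)) stop("performer not found in society")
  dx <- society$x - society$x[i]
  dy <- society$y - society$y[i]
  ok <- dx * dx + dy * dy <= params$radius_local_area^2 &
    society$religiosity > society$religiosity[i] -
      params$parochial_prosociality
  ok[i] <- FALSE
  society$id[ok]
}

#' Apply one prosocial act
#'
#' Reference implementation of a single act, operating on the society from
#' R: the performer loses `pb_dec_insec_self` insecurity and
#' `pb_wellbeing_cost` wellbeing (both floored at 0) and, if still of
#' socialisation age, gains `pb_inc_rel_self` religiosity (capped at 1); up
#' to `num_neigh_benefited` beneficiaries are then drawn uniformly without
#' replacement from [eligible_beneficiaries()] and receive the neighbour
#' effects. Anxiety is recomputed for every touched agent. Beneficiary
#' sampling uses R's RNG (not the engine stream); the compiled yearly sweep
#' in [pb_stage()] is the production path.
#'
#' @param performer_id id of the performing agent (must satisfy the age and
#'   trigger preconditions; checked).
#' @param society a `society`.
#' @param params a [behaviour_params()] block.
#' @return the updated society, with attribute `beneficiaries` (ids).
#' @export
perform_prosocial_act <- function(performer_id, society, params) {
  i <- match(performer_id, society$id)
  if (is.na(i)) stop("performer not found in society")
  if (society$age[i] < params$pb_min_age)
    stop("performer is below the minimum prosocial-behaviour age")
  anx <- society$insecurity[i] * society$sensitivity[i]
  if (!pb_trigger(anx, society$religiosity[i], params$pb_threshold))
    stop("performer does not satisfy the trigger precondition")
  elig <- eligible_beneficiaries(performer_id, society, params)
  society$insecurity[i] <- max(0, society$insecurity[i] -
                                 params$pb_dec_insec_self)
  society$wellbeing[i] <- max(0, society$wellbeing[i] -
                                params$pb_wellbeing_cost)
  if (society$age[i] <= params$socialisation_max_age)
    society$religiosity[i] <- min(1, society$religiosity[i] +
                                    params$pb_inc_rel_self)
  society$anxiety[i] <- society$insecurity[i] * society$sensitivity[i]
  k <- min(params$num_neigh_benefited, length(elig))
  chosen <- if (k > 0) sample(elig, k) else integer(0)
  for (id in chosen) {
    j <- match(id, society$id)
    society$insecurity[j] <- max(0, society$insecurity[j] -
                                   params$pb_dec_insec_neigh)
    if (society$age[j] <= params$socialisation_max_age)
      society$religiosity[j] <- min(1, society$religiosity[j] +
                                      params$pb_inc_rel_neigh)
    society$anxiety[j] <- society$insecurity[j] * society$sensitivity[j]
  }
  attr(society, "beneficiaries") <- chosen
  society
}

#' Yearly religiosity decay
#'
#' Agents still inside the decay window (younger than 26, and at least
#' `min_age` if a lower bound is set) lose a fraction `rel_dec_perc` of
#' their religiosity each year; everyone older keeps theirs unchanged, so
#' adult religiosity is frozen apart from prosocial reinforcement received
#' while young. Vectorised.
#'
#' @param religiosity,age numeric vectors.
#' @param rel_dec_perc decay fraction in \[0, 1\].
#' @param min_age lower bound of the decay window (default 0).
#' @param mode `"multiplicative"` (default) scales by `1 - rel_dec_perc`;
#'   `"additive"` subtracts it, floored at 0.
#' @return the decayed religiosity vector.
#' @export
#' @examples
#' decay_religiosity(0.5, 20, 0.1)  # 0.45
decay_religiosity <- function(religiosity, age, rel_dec_perc, min_age = 0,
                              mode = c("multiplicative", "additive")) {
  mode <- match.arg(mode)
  if (rel_dec_perc < 0 || rel_dec_perc > 1)
    stop("rel_dec_perc must lie in [0, 1]")
  in_window <- age < 26 & age >= min_age
  out <- religiosity
  if (mode == "multiplicative")
    out[in_window] <- out[in_window] * (1 - rel_dec_perc)
  else
    out[in_window] <- pmax(0, out[in_window] - rel_dec_perc)
  out
}
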