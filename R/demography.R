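polyval <- function(coef, x) {
  acc <- rep(0, length(x))
  for (k in rev(seq_along(coef))) acc <- acc * x + coef[k]
  acc
}

#' Initial wellbeing as a polynomial of age
#'
#' Evaluates the configured age polynomial (intercept-first coefficients)
#' and clamps the result into \[0, 1\]. The shipped default mirrors a
#' mid-20th-century survival curve: high through childhood and adulthood,
#' declining at old ages.
#'
#' @param age ages in \[0, 100\].
#' @param curve polynomial coefficient vector, defaults to
#'   [default_init_wb_curve()].
#' @return wellbeing values in \[0, 1\].
#' @export
initial_wellbeing <- function(age, curve = default_init_wb_curve()) {
  if (any(age < 0 | age > 100, na.rm = TRUE))
    stop("age must lie in [0, 100]")
  pmin(1, pmax(0, polyval(curve, age)))
}

#' Age-linked yearly wellbeing delta
#'
#' With `u = (age - wb_age_threshold) / (100 - wb_age_threshold)`, ages at
#' or above the threshold receive `C - 4C * u^Exp_loss` (equal to `C` at
#' the threshold and `-3C` at age 100); younger ages use the signed-power
#' extension `C + 4C * |u|^Exp_gain`, largest at age 0 and decreasing to
#' `C` at the threshold, so the life-course curve is continuous and
#' hump-shaped. The result is added to wellbeing (with clamping) by the
#' engine.
#'
#' @param age ages (years).
#' @param params a [demography_params()] block.
#' @return signed deltas.
#' @export
wb_age_delta <- function(age, params = demography_params()) {
  cfg <- sim_config(demography = params)
  as.numeric(cpp_wb_age_delta(as.numeric(age), engine_params(cfg)))
}

#' Insecurity-linked yearly wellbeing delta
#'
#' Piecewise linear and continuous: `+wb_max_inc` at insecurity 0,
#' declining to 0 at `wb_insec_threshold`, then declining further to
#' `-wb_max_dec` at insecurity 1. (The flag `wb_insec_printed_form` in
#' [demography_params()] switches the gain branch to a variant whose gain
#' grows with insecurity, retained for robustness checks.)
#'
#' @param insecurity values in \[0, 1\].
#' @param params a [demography_params()] block.
#' @return signed deltas.
#' @export
wb_insecurity_delta <- function(insecurity, params = demography_params()) {
  if (any(insecurity < 0 | insecurity > 1, na.rm = TRUE))
    stop("insecurity must lie in [0, 1]")
  cfg <- sim_config(demography = params)
  as.numeric(cpp_wb_insec_delta(as.numeric(insecurity), engine_params(cfg)))
}

#' Yearly death probability as a function of wellbeing
#'
#' Evaluates the mortality polynomial at the (clamped) wellbeing and clamps
#' the result into \[0, 1\]. The shipped default is monotone decreasing,
#' near 1 at wellbeing 0 and near 0 at wellbeing 1.
#'
#' @param wellbeing values (clamped into \[0, 1\] before evaluation).
#' @param curve polynomial coefficient vector, defaults to
#'   [default_mortality_curve()].
#' @return probabilities in \[0, 1\].
#' @export
death_probability <- function(wellbeing, curve = default_mortality_curve()) {
  w <- pmin(1, pmax(0, wellbeing))
  pmin(1, pmax(0, polyval(curve, w)))
}

#' Yearly reproduction probability of a married couple
#'
#' The couple's wellbeing and insecurity are combined into the weighted
#' average
#' `x = (avg_wellbeing * importance_wb + avg_insecurity * importance_insec) /
#' (importance_wb + importance_insec)` and passed through the sigmoid
#' `1 / (1 + exp(-b (x - a)))`, so the probability is 0.5 exactly at
#' `x = a` and increases with both wellbeing and insecurity: insecure
#' environments raise the propensity to reproduce.
#'
#' @param avg_wellbeing,avg_insecurity couple means, in \[0, 1\].
#' @param params a [demography_params()] block.
#' @return probabilities in (0, 1).
#' @export
reproduction_probability <- function(avg_wellbeing, avg_insecurity,
                                     params = demography_params()) {
  x <- (avg_wellbeing * params$importance_wb +
          avg_insecurity * params$importance_insec) /
    (params$importance_wb + params$importance_insec)
  1 / (1 + exp(-params$rep_curve_shape * (x - params$rep_mid_threshold)))
}
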