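# Trend tests and trajectory classification. Societies are classified on
# the coarse series sampled every 25 years from year 200 onwards (17 points
# over a 600-year run): dying / surviving / thriving by the sign of a
# significant Pearson correlation between population size and year, and the
# religiosity trend by the same test on mean religiosity.

#' Pearson trend test of a sampled series
#'
#' Pearson correlation with the classical two-sided p-value from the
#' t transform with n - 2 degrees of freedom. A degenerate series (fewer
#' than 3 complete points, or zero variance in either variable) has an
#' undefined correlation and is reported as non-significant (r reported as
#' NA and p as 1).
#'
#' @param years,values numeric vectors of equal length.
#' @return list with `r`, `p`, and `sign` (-1, 0, 1; 0 when undefined).
#' @export
pearson_trend_test <- function(years, values) {
  if (length(years) != length(values))
    stop("years and values must have equal length")
  ok <- stats::complete.cases(years, values)
  x <- years[ok]; y <- values[ok]
  if (length(x) < 3)
    stop("trend test needs at least 3 complete points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = 1, sign = 0))
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  r <- unname(ct$estimate)
  list(r = r, p = ct$p.value, sign = sign(r))
}

trend_series <- function(traj, column, start_year = 200) {
  s <- sampled_series(traj)
  out <- s[s$year >= start_year, c("year", column)]
  # horizons shorter than the standard trend window fall back to the whole
  # sampled series
  if (nrow(out) < 3) out <- s[, c("year", column)]
  out
}

#' Classify a population trajectory as dying, surviving or thriving
#'
#' Applies [pearson_trend_test()] to the sampled population series from
#' `start_year` on: a significant negative correlation (p below the
#' threshold) is `"dying"`, significant positive `"thriving"`, anything
#' else `"surviving"`. An extinct society (population 0 at the horizon) is
#' always `"dying"`, and a run halted at the population cap (it outgrew 20
#' times its initial size and was still growing) is `"thriving"` by
#' convention.
#'
#' @param traj a `trajectory`.
#' @param p_threshold significance level (0.1 by convention here).
#' @param start_year first year of the tested series.
#' @return one of `"dying"`, `"surviving"`, `"thriving"`.
#' @export
classify_population_trajectory <- function(traj, p_threshold = 0.1,
                                           start_year = 200) {
  s <- trend_series(traj, "pop", start_year)
  if (s$pop[nrow(s)] == 0) return("dying")
  if (isTRUE(attr(traj, "capped"))) return("thriving")
  tt <- pearson_trend_test(s$year, s$pop)
  if (!is.na(tt$r) && tt$p < p_threshold)
    return(if (tt$sign < 0) "dying" else "thriving")
  "surviving"
}

#' Classify the religiosity trend of a trajectory
#'
#' Same test on the sampled mean-religiosity series: significant negative
#' is `"declining"`, significant positive `"increasing"`, otherwise
#' `"stable"` (including degenerate constant series).
#'
#' @inheritParams classify_population_trajectory
#' @return one of `"declining"`, `"increasing"`, `"stable"`.
#' @export
classify_religiosity_trajectory <- function(traj, p_threshold = 0.1,
                                            start_year = 200) {
  s <- trend_series(traj, "mean_rel", start_year)
  ok <- !is.na(s$mean_rel)
  if (sum(ok) < 3) return("stable")
  tt <- pearson_trend_test(s$year[ok], s$mean_rel[ok])
  if (!is.na(tt$r) && tt$p < p_threshold)
    return(if (tt$sign < 0) "declining" else "increasing")
  "stable"
}

#' Success rule
#'
#' A society counts as successful when its population size strictly exceeds
#' 2500 at the horizon (the initial population is 1000, and the cut sits
#' above the reference model's third quartile).
#'
#' @param traj a `trajectory`.
#' @param threshold population cut (default 2500).
#' @return logical.
#' @export
is_successful <- function(traj, threshold = 2500) {
  s <- sampled_series(traj)
  s$pop[nrow(s)] > threshold
}

#' Pace of religiosity decline of a thriving society
#'
#' Thriving societies with declining religiosity (TSDR) are graded by how
#' far religiosity has fallen by the horizon: every TSDR belongs to the
#' slow/medium/fast class; those ending below mean religiosity 0.5 are also
#' medium/fast; below 0.125, also fast. The classes are nested.
#'
#' @param religiosity_trend the value returned by
#'   [classify_religiosity_trajectory()] (must be `"declining"`).
#' @param final_mean_rel mean religiosity at the horizon.
#' @return named logical vector with elements `smf`, `mf`, `f`.
#' @export
pace_category <- function(religiosity_trend, final_mean_rel) {
  if (!identical(religiosity_trend, "declining"))
    stop("pace categories apply only to declining-religiosity societies")
  c(smf = TRUE, mf = final_mean_rel < 0.5, f = final_mean_rel < 0.125)
}
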