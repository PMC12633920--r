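#' Anxiety as the product of insecurity and sensitivity
#'
#' Anxiety is the emotional response to perceived risk: the multiplicative
#' interaction of an agent's accumulated insecurity with its psychological
#' sensitivity to threats. Vectorised.
#'
#' @param insecurity,sensitivity numeric vectors in \[0, 1\].
#' @return `insecurity * sensitivity`, elementwise.
#' @export
#' @examples
#' compute_anxiety(0.5, 0.5)   # 0.25
compute_anxiety <- function(insecurity, sensitivity) {
  if (any(insecurity < 0 | insecurity > 1, na.rm = TRUE))
    stop("insecurity must lie in [0, 1]")
  if (any(sensitivity < 0 | sensitivity > 1, na.rm = TRUE))
    stop("sensitivity must lie in [0, 1]")
  insecurity * sensitivity
}

#' Initialise a society
#'
#' Creates the starting population: ages drawn from a decreasing pyramid
#' (probability of age a proportional to 100 - a over 0..100), gender a fair
#' coin, everyone single, religiosity and sensitivity drawn from
#' Normal(0.5, 0.1) clamped into \[0, 1\], insecurity and anxiety zero,
#' wellbeing set by the age polynomial `init_wb_curve`, and positions uniform
#' over the square habitat.
#'
#' @param config a [sim_config()] object.
#' @param seed integer seed; all randomness of the society (initial draws and
#'   the engine stream carried in `rng_state`) derives from it.
#' @return a `society` object: parallel per-agent vectors plus `year`,
#'   `space_size`, `next_id` and the opaque engine `rng_state`.
#' @export
initialize_society <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  .check_num(seed, "seed", -2^31, 2^31, integer = TRUE)
  set.seed(as.integer(seed))
  n <- config$n_agents
  ages <- sample(0:100, n, replace = TRUE, prob = 100:0)
  rel <- pmin(1, pmax(0, rnorm(n, 0.5, 0.1)))
  sens <- pmin(1, pmax(0, rnorm(n, 0.5, 0.1)))
  soc <- structure(list(
    id = seq_len(n),
    age = as.integer(ages),
    female = as.integer(runif(n) < 0.5),
    married = integer(n),
    partner = integer(n),
    religiosity = rel,
    wellbeing = initial_wellbeing(ages, config$demography$init_wb_curve),
    insecurity = numeric(n),
    sensitivity = sens,
    anxiety = numeric(n),
    x = runif(n, 0, config$space_size),
    y = runif(n, 0, config$space_size),
    year = 0L,
    next_id = n + 1L,
    space_size = config$space_size,
    rng_state = cpp_rng_init(abs(as.numeric(seed)) + 1)
  ), class = "society")
  soc
}

#' Population size of a society
#' @param society a `society` object.
#' @return integer count of living agents.
#' @export
population_size <- function(society) length(society$id)

#' @export
print.society <- function(x, ...) {
  cat(sprintf("<society> year %d, %d agents, mean religiosity %.3f\n",
              x$year, length(x$id),
              if (length(x$id)) mean(x$religiosity) else NA_real_))
  invisible(x)
}

# one-row summary used when recording from R-level stepping
society_summary <- function(society, births = 0L, deaths = 0L,
                            pb_count = 0L) {
  n <- length(society$id)
  data.frame(
    year = society$year,
    pop = n,
    mean_rel = if (n) mean(society$religiosity) else NA_real_,
    mean_ins = if (n) mean(society$insecurity) else NA_real_,
    mean_wb = if (n) mean(society$wellbeing) else NA_real_,
    births = births, deaths = deaths, pb_count = pb_count
  )
}
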