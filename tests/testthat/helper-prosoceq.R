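# Shared fixtures: small, fast configurations and hand-built societies /
# trajectories. Everything is generated in code; no stored data.

# a small society and short horizon so unit tests stay fast
tiny_config <- function(n_agents = 200L, horizon = 50L,
                        record_interval = NULL,
                        threat_start_year = 10L, ...) {
  if (is.null(record_interval))
    record_interval <- prosoceq:::gcd_interval(horizon)
  sim_config(n_agents = n_agents,
             schedule = schedule_config(horizon = horizon,
                                        record_interval = record_interval,
                                        threat_start_year = threat_start_year,
                                        ci_start_year = min(
                                          max(threat_start_year, 20L),
                                          horizon)),
             ...)
}

# hand-placed society: agents at given coordinates with given traits
make_society <- function(x, y, age, religiosity, insecurity = 0,
                         sensitivity = 0.5, wellbeing = 0.8,
                         female = NULL, space_size = 500) {
  n <- length(x)
  rec <- function(v) rep_len(v, n)
  if (is.null(female)) female <- rep(c(1L, 0L), length.out = n)
  structure(list(
    id = seq_len(n), age = as.integer(rec(age)),
    female = as.integer(rec(female)), married = integer(n),
    partner = integer(n),
    religiosity = rec(religiosity), wellbeing = rec(wellbeing),
    insecurity = rec(insecurity), sensitivity = rec(sensitivity),
    anxiety = rec(insecurity) * rec(sensitivity),
    x = as.numeric(x), y = as.numeric(y),
    year = 0L, next_id = n + 1L, space_size = space_size,
    rng_state = prosoceq:::cpp_rng_init(99)
  ), class = "society")
}

# build a trajectory object from a sampled-scale series (one value per
# record_interval years); yearly rows are linearly interpolated
make_trajectory <- function(pop, mean_rel = NULL, record_interval = 25L) {
  n <- length(pop)
  years <- seq(0L, by = record_interval, length.out = n)
  if (is.null(mean_rel)) mean_rel <- rep(0.5, n)
  yearly <- data.frame(
    year = years, pop = pop, mean_rel = mean_rel,
    mean_ins = 0, mean_wb = 0.8, births = 0, deaths = 0, pb_count = 0)
  prosoceq:::new_trajectory(yearly, record_interval)
}

# from-definition Pearson r and two-sided p (textbook t transform)
brute_force_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tt), df = n - 2))
}

expect_society_valid <- function(soc) {
  n <- length(soc$id)
  expect_true(all(lengths(soc[c("age", "female", "married", "partner",
                                "religiosity", "wellbeing", "insecurity",
                                "sensitivity", "anxiety", "x", "y")]) == n))
  for (f in c("religiosity", "wellbeing", "insecurity", "sensitivity",
              "anxiety"))
    expect_true(all(soc[[f]] >= 0 & soc[[f]] <= 1), label = f)
  expect_equal(soc$anxiety, soc$insecurity * soc$sensitivity,
               tolerance = 1e-12)
  expect_true(all(soc$x >= 0 & soc$x <= soc$space_size))
  expect_true(all(soc$y >= 0 & soc$y <= soc$space_size))
  # marriage reciprocity
  idx <- match(soc$partner, soc$id)
  married <- soc$married == 1L
  expect_true(all(soc$partner[!married] == 0L))
  expect_true(all(!is.na(idx[married])))
  if (any(married))
    expect_true(all(soc$partner[idx[married]] == soc$id[married]))
  invisible(soc)
}
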