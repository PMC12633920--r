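test_that("the Latin hypercube stratifies every parameter", {
  ranges <- data.frame(parameter = c("a", "b"), min = c(0, 10),
                       max = c(1, 20))
  d <- latin_hypercube_design(ranges, 10, seed = 4, integer_params = NULL)
  expect_equal(nrow(d), 10)
  # exactly one point per decile of each range
  expect_setequal(findInterval(d$a, seq(0, 1, 0.1), rightmost.closed = TRUE),
                  1:10)
  expect_setequal(findInterval(d$b, seq(10, 20, 1), rightmost.closed = TRUE),
                  1:10)
  expect_true(all(d$a >= 0 & d$a <= 1 & d$b >= 10 & d$b <= 20))
  # deterministic under the seed
  expect_identical(latin_hypercube_design(ranges, 10, seed = 4,
                                          integer_params = NULL), d)
  expect_error(latin_hypercube_design(
    data.frame(parameter = "a", min = 1, max = 0), 5, 1), "min")
})

test_that("the standard sweep ranges narrow as documented", {
  broad <- sweep_ranges("broad")
  expect_equal(nrow(broad), 9)
  focused <- sweep_ranges("focused")
  get <- function(df, p, col) df[[col]][df$parameter == p]
  expect_equal(get(focused, "pb_threshold", "max"), 0.05)
  expect_equal(get(focused, "pb_wellbeing_cost", "max"), 0.025)
  expect_equal(get(focused, "pb_dec_insec_self", "min"), 0.25)
  expect_equal(get(focused, "num_neigh_benefited", "min"), 5)
  ci <- sweep_ranges("ci")
  expect_equal(get(ci, "threat_value", "max"), 0.3)
  expect_equal(get(ci, "rel_dec_perc", "max"), 0.25)
  expect_setequal(setdiff(ci$parameter, focused$parameter),
                  c("parochial_prosociality", "ci_wb_cost", "ci_benefit"))
  # designs respect the declared bounds and integer rounding
  d <- latin_hypercube_design(focused, 50, seed = 2)
  expect_true(all(d$pb_threshold <= 0.05))
  expect_true(all(d$num_neigh_benefited == round(d$num_neigh_benefited)))
})

test_that("grid designs enumerate the full cross product", {
  g <- grid_design(list(a = 1:3, b = c(0.1, 0.2)))
  expect_equal(nrow(g), 6)
  expect_equal(sort(unique(g$a)), 1:3)
})

test_that("the trend test agrees with the from-definition formula", {
  set.seed(10)
  for (k in 1:25) {
    x <- seq(200, 600, 25)
    y <- rnorm(17, mean = 1000 + k * x / 100, sd = 300)
    got <- pearson_trend_test(x, y)
    want <- brute_force_pearson(x, y)
    expect_equal(got$r, want$r, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-12)
  }
  # perfect trend and degenerate constant series
  up <- pearson_trend_test(x, seq_len(17))
  expect_equal(up$r, 1)
  expect_equal(up$sign, 1)
  flat <- pearson_trend_test(x, rep(5, 17))
  expect_true(is.na(flat$r))
  expect_equal(flat$p, 1)
  expect_error(pearson_trend_test(1:2, 1:2), "3 complete points")
})

test_that("population trajectories classify by the significance rule", {
  # linear growth after year 200
  pop <- c(rep(1000, 8), seq(1000, 3000, length.out = 17))
  expect_equal(classify_population_trajectory(make_trajectory(pop)),
               "thriving")
  # extinction mid-run: zero-padded series tests as declining
  popx <- c(rep(1000, 8), seq(900, 0, length.out = 5), rep(0, 12))
  expect_equal(classify_population_trajectory(make_trajectory(popx)),
               "dying")
  # extinct before the trend window: still dying by the extinction rule
  pop0 <- c(rep(1000, 4), rep(0, 21))
  expect_equal(classify_population_trajectory(make_trajectory(pop0)),
               "dying")
  # white noise around a constant: surviving in the vast majority of seeds
  set.seed(77)
  lab <- replicate(200, classify_population_trajectory(
    make_trajectory(c(rep(1500, 8), round(rnorm(17, 1500, 80))))))
  expect_gte(mean(lab == "surviving"), 0.85)
})

test_that("religiosity trends classify including degenerate cases", {
  rel_fall <- c(rep(0.9, 8), seq(0.9, 0.2, length.out = 17))
  expect_equal(classify_religiosity_trajectory(
    make_trajectory(rep(2000, 25), rel_fall)), "declining")
  expect_equal(classify_religiosity_trajectory(
    make_trajectory(rep(2000, 25), rep(1, 25))), "stable")
  rel_up <- c(rep(0.2, 8), seq(0.2, 1, length.out = 17))
  expect_equal(classify_religiosity_trajectory(
    make_trajectory(rep(2000, 25), rel_up)), "increasing")
})

test_that("the success rule is strict at the population cut", {
  expect_false(is_successful(make_trajectory(c(rep(1000, 24), 2500))))
  expect_true(is_successful(make_trajectory(c(rep(1000, 24), 2501))))
  expect_false(is_successful(make_trajectory(c(rep(1000, 24), 0))))
})

test_that("pace categories are nested and guarded", {
  expect_equal(pace_category("declining", 0.4),
               c(smf = TRUE, mf = TRUE, f = FALSE))
  expect_equal(pace_category("declining", 0.1),
               c(smf = TRUE, mf = TRUE, f = TRUE))
  expect_equal(pace_category("declining", 0.6),
               c(smf = TRUE, mf = FALSE, f = FALSE))
  expect_error(pace_category("stable", 0.4), "declining")
})

test_that("the classification pipeline equals a brute-force reimplementation", {
  set.seed(42)
  n_cases <- 1000
  agree <- TRUE
  for (k in seq_len(n_cases)) {
    kind <- k %% 4
    pop <- switch(kind + 1,
      round(pmax(0, cumsum(c(1500, rnorm(24, 0, 120))))),        # random walk
      round(seq(1000, 1000 + sample(c(-900, 2000), 1), length.out = 25)),
      rep(sample(c(0, 1200, 3000), 1), 25),                       # constant
      round(pmax(0, 1500 + 300 * sin(1:25 / 3) + rnorm(25, 0, 50))))
    pop[pop < 0] <- 0
    if (any(pop == 0)) pop[which.max(pop == 0):25] <- 0   # absorbing state
    rel <- pmin(1, pmax(0, 0.5 + cumsum(rnorm(25, 0, 0.02))))
    traj <- make_trajectory(pop, rel)
    got_pop <- classify_population_trajectory(traj)
    got_rel <- classify_religiosity_trajectory(traj)
    # from-definition re-derivation
    sel <- seq(0, 600, 25) >= 200
    yy <- seq(0, 600, 25)[sel]
    want_pop <- if (pop[25] == 0) "dying" else {
      if (sd(pop[sel]) == 0) "surviving" else {
        bf <- brute_force_pearson(yy, pop[sel])
        if (bf$p < 0.1 && bf$r < 0) "dying"
        else if (bf$p < 0.1 && bf$r > 0) "thriving" else "surviving"
      }
    }
    want_rel <- if (sd(rel[sel]) == 0) "stable" else {
      bf <- brute_force_pearson(yy, rel[sel])
      if (bf$p < 0.1 && bf$r < 0) "declining"
      else if (bf$p < 0.1 && bf$r > 0) "increasing" else "stable"
    }
    if (!identical(got_pop, want_pop) || !identical(got_rel, want_rel))
      agree <- FALSE
  }
  expect_true(agree)
})

test_that("experiment batches are complete, labelled and reproducible", {
  ranges <- sweep_ranges("focused")
  design <- latin_hypercube_design(ranges, 4, seed = 6)
  cfg <- tiny_config(n_agents = 150L, horizon = 50L, record_interval = 25L,
                     threat_start_year = 10L)
  res <- run_experiment_batch(design, cfg, seed = 6)
  expect_equal(nrow(res), 12)   # 4 samples x 3 schedules
  expect_true(all(ranges$parameter %in% names(res)))
  expect_true(all(c("schedule", "seed", "final_pop", "success", "pop_trend",
                    "rel_trend", "pace_smf") %in% names(res)))
  # same design seed shares run seeds across schedules (paired comparisons)
  expect_equal(as.numeric(tapply(res$seed, res$design_index, sd)), rep(0, 4))
  res2 <- run_experiment_batch(design, cfg, seed = 6)
  expect_identical(res, res2)
  # parallel execution returns the identical table
  res_par <- run_experiment_batch(design, cfg, seed = 6, cores = 2L)
  expect_identical(res, res_par)
  # pace flags are nested
  expect_true(all(res$pace_f <= res$pace_mf & res$pace_mf <= res$pace_smf))
  # category shares sum to one hundred within each schedule
  shares <- category_shares(res, "pop_trend")
  expect_equal(unname(colSums(shares)), rep(100, 3))
})
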