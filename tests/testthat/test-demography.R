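test_that("initial wellbeing follows the configured age curve", {
  expect_gt(initial_wellbeing(20), initial_wellbeing(90))
  all_ages <- initial_wellbeing(0:100)
  expect_true(all(all_ages >= 0 & all_ages <= 1))
  expect_equal(initial_wellbeing(0:100, curve = 0.8), rep(0.8, 101))
  expect_error(initial_wellbeing(120), "age")
})

test_that("the age-linked wellbeing delta matches its closed form", {
  p <- demography_params(wb_age_threshold = 50, wb_intercept_C = 0.02,
                         wb_exp_gain = 2, wb_exp_loss = 3)
  C <- 0.02
  expect_equal(wb_age_delta(50, p), C)                      # u = 0
  expect_equal(wb_age_delta(100, p), -3 * C)                # u = 1
  # zero crossing of the loss regime at u = (1/4)^(1/Exp2)
  u0 <- (1 / 4)^(1 / 3)
  age0 <- 50 + u0 * 50
  expect_equal(wb_age_delta(age0, p), 0, tolerance = 1e-12)
  # signed-power extension below the threshold: C + 4C |u|^Exp1
  expect_equal(wb_age_delta(0, p), C + 4 * C * 1)           # u = -1
  expect_equal(wb_age_delta(25, p), C + 4 * C * 0.5^2)
  # monotone decreasing across the whole age range for these shapes
  expect_true(all(diff(wb_age_delta(0:100, p)) <= 1e-12))
})

test_that("the insecurity-linked wellbeing delta honours its endpoints", {
  p <- demography_params()   # threshold 0.1, max dec 0.25
  expect_equal(wb_insecurity_delta(0, p), p$wb_max_inc)
  expect_equal(wb_insecurity_delta(0.1, p), 0)
  expect_equal(wb_insecurity_delta(1, p), -0.25)
  expect_equal(wb_insecurity_delta(0.55, p), -0.125)   # halfway to the floor
  # continuity at the threshold and monotone non-increase
  eps <- 1e-9
  expect_equal(wb_insecurity_delta(0.1 - eps, p),
               wb_insecurity_delta(0.1 + eps, p), tolerance = 1e-6)
  grid <- wb_insecurity_delta(seq(0, 1, 0.01), p)
  expect_true(all(diff(grid) <= 1e-12))
  expect_error(wb_insecurity_delta(1.2, p), "insecurity")
})

test_that("the default mortality curve has the documented silhouette", {
  expect_gte(death_probability(0), 0.9)
  expect_lte(death_probability(1), 0.02)
  expect_gte(death_probability(0.2), death_probability(0.8))
  grid <- death_probability(seq(0, 1, 0.01))
  expect_true(all(grid >= 0 & grid <= 1))
  expect_true(all(diff(grid) <= 1e-12))
})

test_that("reproduction probability is the sigmoid of the weighted average", {
  p <- demography_params(rep_mid_threshold = 0.5, rep_curve_shape = 10)
  # probability one half exactly at the midpoint
  expect_equal(reproduction_probability(0.5, 0.5, p), 0.5)
  expect_equal(reproduction_probability(0.75, 0, p),
               1 / (1 + exp(-10 * (0.5 - 0.5))))
  # weighted average with weights (1, 0.5): x = (0.6 + 0.1) / 1.5
  x <- (0.6 * 1 + 0.2 * 0.5) / 1.5
  expect_equal(x, 0.7 / 1.5)
  expect_equal(reproduction_probability(0.6, 0.2, p),
               1 / (1 + exp(-10 * (x - 0.5))))
  # steep curve saturates above the midpoint
  steep <- demography_params(rep_mid_threshold = 0.5, rep_curve_shape = 500)
  expect_gt(reproduction_probability(0.6, 0.6, steep), 0.999)
  # monotone in both wellbeing and insecurity
  expect_gt(reproduction_probability(0.7, 0.2, p),
            reproduction_probability(0.6, 0.2, p))
  expect_gt(reproduction_probability(0.6, 0.4, p),
            reproduction_probability(0.6, 0.2, p))
})

test_that("reproduction transfers wellbeing to the offspring", {
  # one married couple, certain reproduction (steep sigmoid, low midpoint)
  soc <- make_society(x = c(10, 20), y = c(10, 10), age = c(30, 32),
                      religiosity = c(0.3, 0.9), insecurity = c(0.2, 0.6),
                      wellbeing = c(0.8, 0.6), female = c(1L, 0L))
  soc$married <- c(1L, 1L)
  soc$partner <- c(2L, 1L)
  d <- demography_params(rep_cost = 0.05, rep_mid_threshold = 0.01,
                         rep_curve_shape = 500)
  cfg <- sim_config(demography = d)
  out <- reproduction_stage(soc, cfg)
  expect_equal(attr(out, "births"), 1L)
  expect_length(out$id, 3L)
  expect_equal(out$wellbeing[1:2], c(0.8, 0.6) * 0.95)
  # offspring wellbeing equals the summed parental losses
  expect_equal(out$wellbeing[3], 0.05 * 0.8 + 0.05 * 0.6)
  expect_equal(out$age[3], 0L)
  expect_equal(out$married[3], 0L)
  # traits copied wholesale from exactly one parent
  trip <- c(out$religiosity[3], out$insecurity[3], out$sensitivity[3])
  par1 <- c(0.3, 0.2, 0.5); par2 <- c(0.9, 0.6, 0.5)
  expect_true(isTRUE(all.equal(trip, par1)) || isTRUE(all.equal(trip, par2)))
  expect_equal(out$anxiety[3], out$insecurity[3] * out$sensitivity[3])
})

test_that("reproduction preconditions are enforced by the engine", {
  base <- make_society(x = c(10, 20), y = c(10, 10), age = c(30, 32),
                       religiosity = 0.5, wellbeing = 0.9,
                       female = c(1L, 0L))
  d <- demography_params(rep_mid_threshold = 0.01, rep_curve_shape = 500)
  cfg <- sim_config(demography = d)
  # unmarried: no offspring
  expect_equal(attr(reproduction_stage(base, cfg), "births"), 0L)
  # married but female over 49: no offspring
  old <- base; old$married <- c(1L, 1L); old$partner <- c(2L, 1L)
  old$age <- c(55L, 32L)
  expect_equal(attr(reproduction_stage(old, cfg), "births"), 0L)
})

test_that("marriage respects age and age-difference rules", {
  soc <- make_society(x = 1:6 * 10, y = rep(5, 6),
                      age = c(20, 24, 14, 10, 60, 90),
                      religiosity = 0.5,
                      female = c(1L, 0L, 1L, 0L, 1L, 0L))
  cfg <- sim_config(demography = demography_params(marriage_age_diff = 5))
  out <- form_marriages(soc, cfg)
  expect_society_valid(out)
  # the 20- and 24-year-olds can only match each other (diff 4 <= 5)
  expect_equal(out$married[1:2], c(1L, 1L))
  expect_equal(out$partner[1], 2L)
  # 14-year-old is under the strict minimum and never matches
  expect_equal(out$married[3], 0L)
  # the 60- and 90-year-olds have no counterpart within 5 years
  expect_equal(out$married[5:6], c(0L, 0L))
  # already-married pairs are left untouched
  again <- form_marriages(out, cfg)
  expect_equal(again$partner[1:2], out$partner[1:2])
})

test_that("mortality removes the dead and widows the survivors", {
  soc <- make_society(x = 1:4 * 10, y = rep(5, 4), age = 40,
                      religiosity = 0.5,
                      wellbeing = c(0.9, 0.0, 0.9, 0.9),
                      female = c(1L, 0L, 1L, 0L))
  soc$married <- rep(1L, 4)
  soc$partner <- c(2L, 1L, 4L, 3L)
  # deterministic curve: death iff wellbeing below one half
  cfg <- sim_config(demography = demography_params(
    mortality_curve = c(1, -1.999)))
  out <- apply_mortality(soc, cfg)
  expect_equal(attr(out, "deaths"), 1L)
  expect_setequal(out$id, c(1L, 3L, 4L))
  w <- match(1L, out$id)
  expect_equal(out$married[w], 0L)   # widowed
  expect_equal(out$partner[w], 0L)
  expect_equal(out$married[match(3L, out$id)], 1L)
  # certain death empties the society in one year
  cfg2 <- sim_config(demography = demography_params(mortality_curve = 1))
  expect_length(apply_mortality(soc, cfg2)$id, 0L)
})

test_that("engine mortality matches a Bernoulli oracle in distribution", {
  # constant death probability 0.2 for everyone; compare the deaths count
  # distribution over replicates with a binomial chi-square fit
  n <- 500L
  cfg <- sim_config(demography = demography_params(mortality_curve = 0.2))
  soc0 <- make_society(x = runif(n, 0, 500), y = runif(n, 0, 500), age = 30,
                       religiosity = 0.5, wellbeing = 0.7)
  deaths <- integer(200)
  for (r in 1:200) {
    soc0$rng_state <- prosoceq:::cpp_rng_init(r)
    deaths[r] <- attr(apply_mortality(soc0, cfg), "deaths")
  }
  # bin the observed counts and test against Binomial(n, 0.2)
  brk <- c(-Inf, 85, 93, 100, 107, 115, Inf)
  obs <- table(cut(deaths, brk))
  pr <- diff(pbinom(c(-Inf, 85, 93, 100, 107, 115, Inf), n, 0.2))
  gof <- suppressWarnings(chisq.test(as.numeric(obs), p = pr))
  expect_gt(gof$p.value, 0.001)
  expect_lt(abs(mean(deaths) - n * 0.2), 3 * sqrt(n * 0.2 * 0.8 / 200))
})

test_that("wellbeing at full health keeps yearly deaths rare", {
  n <- 1000L
  soc <- make_society(x = runif(n, 0, 500), y = runif(n, 0, 500), age = 30,
                      religiosity = 0.5, wellbeing = 1)
  out <- apply_mortality(soc, sim_config())
  expect_lte(attr(out, "deaths"), 0.02 * n + 5)
})
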