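# Virtual populations, GMR statistics and bioequivalence trial mechanics.

test_that("population generation is seeded and respects its spec", {
  spec <- population_spec(n_subjects = 59, age_range = c(20, 60),
                          proportion_female = 0.5, seed = 7)
  p1 <- generate_population(spec)
  p2 <- generate_population(spec)
  expect_identical(p1, p2)
  ages <- vapply(p1, `[[`, numeric(1), "age")
  expect_true(all(ages >= 20 & ages <= 60))
  sexes <- vapply(p1, `[[`, character(1), "sex")
  expect_identical(sum(sexes == "F"), 30L)  # round half up of 29.5
  expect_true(all(vapply(p1, `[[`, numeric(1), "body_weight") > 0))
  # a different seed gives a different population
  p3 <- generate_population(population_spec(n_subjects = 59, seed = 8))
  expect_false(identical(vapply(p1, `[[`, numeric(1), "body_weight"),
                         vapply(p3, `[[`, numeric(1), "body_weight")))
})

test_that("zero variability collapses the population onto the typical subject", {
  spec <- population_spec(n_subjects = 5, age_range = c(40, 40),
                          proportion_female = 0,
                          variability = zero_variability(),
                          occasion_cv = 0, seed = 3)
  pop <- generate_population(spec)
  ref <- pop[[1]]
  for (s in pop[-1]) {
    for (f in c("body_weight", "height", "liver_mass", "hepatic_blood_flow",
                "cl_u_int_multiplier", "fu_plasma_multiplier",
                "gastric_mrt_multiplier", "si_transit_multiplier",
                "colon_mrt_multiplier", "stomach_ph")) {
      expect_equal(s[[f]], ref[[f]], tolerance = 1e-12)
    }
  }
  expect_equal(ref$cl_u_int_multiplier, 1, tolerance = 1e-12)
  expect_equal(ref$stomach_ph, 1.5)
})

test_that("demographics generator fixes the female count by round half up", {
  d <- make_demographics(59, c(20, 60), pct_female = 0.57, seed = 9)
  expect_identical(nrow(d), 59L)
  expect_identical(sum(d$sex == "F"), 34L)  # 0.57 * 59 = 33.6
  expect_true(all(d$age >= 20 & d$age <= 60))
  expect_identical(d, make_demographics(59, c(20, 60), 0.57, seed = 9))
})

test_that("GMR statistics match hand-computed examples", {
  # 4 paired ratios: GMR = exp(mean log ratio)
  ref <- c(10, 10, 10, 10)
  test <- c(1.0, 1.1, 0.9, 1.05) * ref
  r <- gmr_ci(test, ref, "crossover", parameter = "cmax")
  expect_equal(r$gmr, 100 * exp(mean(log(c(1.0, 1.1, 0.9, 1.05)))),
               tolerance = 1e-12)
  expect_equal(r$gmr, 100.97, tolerance = 1e-4)
  expect_true(r$ci90_low <= r$gmr && r$gmr <= r$ci90_high)
  # identical arms: GMR exactly 100, degenerate CI
  same <- c(3, 5, 8, 13)
  r2 <- gmr_ci(same, same, "crossover")
  expect_identical(r2$gmr, 100)
  expect_identical(r2$ci90_low, 100)
  expect_identical(r2$ci90_high, 100)
  expect_true(r2$pass_be)
  # permutation invariance of the paired analysis
  o <- c(2, 4, 1, 3)
  r3 <- gmr_ci(test[o], ref[o], "crossover")
  expect_equal(r3$gmr, r$gmr, tolerance = 1e-12)
  expect_equal(r3$ci90_low, r$ci90_low, tolerance = 1e-12)
  expect_error(gmr_ci(1.2, 1.1, "crossover"), "at least 2")
  expect_error(gmr_ci(c(-1, 2), c(1, 2), "parallel"), "positive")
})

test_that("crossover CI is never wider than the parallel CI on the same values", {
  set.seed(21)
  for (k in 1:5) {
    ref <- stats::rlnorm(30, log(20), 0.3)
    test <- ref * stats::rlnorm(30, 0, 0.05)
    rx <- gmr_ci(test, ref, "crossover")
    rp <- gmr_ci(test, ref, "parallel")
    expect_lte(log(rx$ci90_high) - log(rx$ci90_low),
               log(rp$ci90_high) - log(rp$ci90_low) + 1e-12)
  }
})

test_that("pass_be is consistent with its CI bounds", {
  set.seed(5)
  for (k in 1:10) {
    ref <- stats::rlnorm(12, log(10), 0.4)
    test <- ref * stats::rlnorm(12, stats::rnorm(1, 0, 0.1), 0.2)
    r <- gmr_ci(test, ref, "crossover")
    expect_identical(r$pass_be, r$ci90_low >= 80 && r$ci90_high <= 125)
  }
})

test_that("identical formulations give GMR 100% through the whole pipeline", {
  cfg <- small_config(n = 4, occasion_cv = 0)
  tab <- config_formulation(cfg, "tablet")
  pop <- generate_population(config_population_spec(cfg))
  tr <- run_be_trial(trial_design("crossover"), tab, tab, pop, cfg, seed = 2)
  for (r in tr$results) {
    expect_equal(r$gmr, 100, tolerance = 1e-9)
    expect_true(r$pass_be)
  }
})

test_that("trial simulation is bit-reproducible under a fixed seed", {
  cfg <- small_config(n = 4)
  susp <- config_formulation(cfg, "suspension")
  tab <- config_formulation(cfg, "tablet")
  pop <- generate_population(config_population_spec(cfg))
  t1 <- run_be_trial(trial_design("crossover"), susp, tab, pop, cfg, seed = 5)
  t2 <- run_be_trial(trial_design("crossover"), susp, tab, pop, cfg, seed = 5)
  expect_identical(t1$results$cmax$gmr, t2$results$cmax$gmr)
  expect_identical(t1$subject_pk$auc_inf, t2$subject_pk$auc_inf)
  tp1 <- run_be_trial(trial_design("parallel"), susp, tab, pop, cfg, seed = 5)
  tp2 <- run_be_trial(trial_design("parallel"), susp, tab, pop, cfg, seed = 5)
  expect_identical(tp1$results$cmax$gmr, tp2$results$cmax$gmr)
})

test_that("between-subject variability widens parallel CIs but not the crossover estimate", {
  v_lo <- default_variability(); v_lo$cl_u_int <- 0.15
  v_hi <- default_variability(); v_hi$cl_u_int <- 0.60
  cfg_lo <- small_config(n = 16, variability = v_lo)
  cfg_hi <- small_config(n = 16, variability = v_hi)
  susp_lo <- config_formulation(cfg_lo, "suspension")
  tab_lo <- config_formulation(cfg_lo, "tablet")
  pop_lo <- generate_population(config_population_spec(cfg_lo))
  pop_hi <- generate_population(config_population_spec(cfg_hi))
  p_lo <- run_be_trial(trial_design("parallel"), susp_lo, tab_lo, pop_lo,
                       cfg_lo, seed = 4)
  p_hi <- run_be_trial(trial_design("parallel"), susp_lo, tab_lo, pop_hi,
                       cfg_hi, seed = 4)
  width <- function(r) log(r$ci90_high) - log(r$ci90_low)
  expect_gt(width(p_hi$results$auc_inf), width(p_lo$results$auc_inf))
  x_lo <- run_be_trial(trial_design("crossover"), susp_lo, tab_lo, pop_lo,
                       cfg_lo, seed = 4)
  x_hi <- run_be_trial(trial_design("crossover"), susp_lo, tab_lo, pop_hi,
                       cfg_hi, seed = 4)
  # the paired point estimate is insensitive to between-subject spread
  expect_equal(x_hi$results$auc_inf$gmr, x_lo$results$auc_inf$gmr,
               tolerance = 0.05)
})

test_that("trial sets derive per-trial seeds deterministically and flag CI excursions", {
  cfg <- small_config(n = 6)
  susp <- config_formulation(cfg, "suspension")
  tab <- config_formulation(cfg, "tablet")
  ts <- trial_set_summary(trial_design("crossover"), susp, tab, cfg,
                          base_seed = 10, n_trials = 2)
  expect_identical(ts$seeds, c(11L, 12L))
  expect_identical(nrow(ts$table), 6L)  # 2 trials x 3 parameters
  expect_identical(ts$flagged, unique(ts$table$trial_id[!ts$table$pass_be]))
  # n_trials = 1 reduces to a single run_be_trial under seed base + 1
  ts1 <- trial_set_summary(trial_design("crossover"), susp, tab, cfg,
                           base_seed = 10, n_trials = 1)
  pop <- generate_population(
    modify_population_spec(config_population_spec(cfg), seed = 11L)
  )
  tr <- run_be_trial(trial_design("crossover"), susp, tab, pop, cfg,
                     seed = 11L)
  expect_equal(ts1$table$gmr_pct[ts1$table$parameter == "cmax"],
               tr$results$cmax$gmr, tolerance = 1e-12)
  path <- tempfile(fileext = ".csv")
  write_trials_csv(ts, path)
  expect_identical(nrow(utils::read.csv(path)), 6L)
})
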