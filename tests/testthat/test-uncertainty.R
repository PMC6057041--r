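test_that("criterion exclusion renormalizes weights and recomputes values", {
  perf <- example_perf()
  w <- example_weights("P1")
  res <- exclude_criterion_sa(perf, w, "enjoyment_of_life")
  expect_equal(round(unname(res$with$values), 3), c(0.722, 0.632))
  # oracle: recompute the weighted sum by hand over the remaining criteria
  set <- attr(perf, "criteria")
  keep <- set$id[set$id != "enjoyment_of_life"]
  std <- standardize_table(perf)
  ww <- unclass(w)[keep] / sum(unclass(w)[keep])
  for (a in c("intervention", "comparator")) {
    manual <- sum(ww * setNames(std[[a]], std$criterion_id)[keep])
    expect_equal(unname(res$without$values[a]), manual, tolerance = 1e-12)
  }
  expect_false("enjoyment_of_life" %in%
                 res$without$contributions$criterion_id)
  expect_error(exclude_criterion_sa(perf, w, "nonexistent"), "not in")
})

test_that("excluding a zero-weight criterion leaves values unchanged", {
  perf <- example_perf()
  ids <- build_core_set()$id
  w0 <- c(0, 0.2, 0.2, 0.1, 0.2, 0.1, 0.1, 0.1)
  w <- weight_vector(setNames(w0, ids))
  res <- exclude_criterion_sa(perf, w, "physical_functioning")
  expect_equal(unname(res$with$values), unname(res$without$values),
               tolerance = 1e-12)
})

test_that("weight-method swap reports both sources and disagreement", {
  perf <- example_perf()
  w1 <- example_weights("P1"); w2 <- example_weights("P2")
  same <- weight_method_swap_sa(perf, w1, w1)
  expect_true(same$agreement)
  expect_equal(same$sources$dce$values, same$sources$swing$values)
  swap <- weight_method_swap_sa(perf, w1, w2)
  expect_false(swap$agreement)
  expect_equal(unname(swap$preferred), c("intervention", "comparator"))
  expect_length(swap$sources$dce$values, 2)
  expect_length(swap$sources$swing$values, 2)
})

test_that("degenerate PSA reproduces the deterministic pipeline exactly", {
  perf <- example_perf()  # all se = 0
  cfg <- psa_config(n_draws = 50, seed = 9, population_size = 1000,
                    budget_grid = c(6e6, 8e6, 9e6))
  draws <- run_psa(perf, cfg, weights = example_weights("P1"))
  v <- overall_value(standardize_table(perf), example_weights("P1"))
  expect_equal(draws$value_intervention, rep(unname(v$values[1]), 50),
               tolerance = 1e-15)
  expect_equal(draws$value_comparator, rep(unname(v$values[2]), 50),
               tolerance = 1e-15)
  expect_equal(draws$cost_intervention, rep(8000, 50))
})

test_that("PSA draws are deterministic given the seed", {
  truth <- table_truth(ses = c(physical_functioning = 4,
                               psychological_wellbeing = 4,
                               social_participation = 0.3,
                               resilience = 0.3, enjoyment_of_life = 0.3,
                               person_centeredness = 0.3,
                               continuity_of_care = 0.3, total_costs = 400))
  perf <- simulate_trial(truth, seed = 2)
  cfg <- psa_config(500, seed = 77, population_size = 1000,
                    budget_grid = seq(6e6, 9e6, 5e5))
  d1 <- run_psa(perf, cfg, weights = example_weights("P1"))
  d2 <- run_psa(perf, cfg, weights = example_weights("P1"))
  expect_identical(d1, d2)
  # draws respect the truncation to scale ranges
  expect_true(all(d1$cost_intervention >= 5500 &
                    d1$cost_intervention <= 8500))
})

test_that("preference probability is stable across independent seeds", {
  truth <- table_truth(ses = 5)  # loose: noisy performance on all criteria
  perf <- simulate_trial(truth, seed = 3)
  w <- example_weights("P1")
  p <- vapply(c(101, 202), function(s) {
    cfg <- psa_config(4000, seed = s, population_size = 1000,
                      budget_grid = 1e7)
    d <- run_psa(perf, cfg, weights = w)
    mean(d$value_intervention > d$value_comparator)
  }, numeric(1))
  mc_se <- sqrt(0.25 / 4000)
  expect_lt(abs(p[1] - p[2]), 3 * (2 * mc_se))
})

test_that("PSA propagates part-worth uncertainty through sampled weights", {
  perf <- example_perf()
  d <- small_design(seed = 3)
  data <- simulate_dce_responses(d, p1_truth_beta(), 150, seed = 41)
  fit <- fit_conditional_logit(d, data)
  cfg <- psa_config(300, seed = 5, population_size = 1000,
                    budget_grid = c(7e6, 9e6))
  draws <- run_psa(perf, cfg, beta = fit)
  # performance is degenerate (se = 0) but weights vary across draws
  expect_gt(stats::sd(draws$value_intervention), 0)
  expect_true(all(draws$value_intervention >= 0 &
                    draws$value_intervention <= 1))
  # zero coefficient covariance collapses to the deterministic weights
  fit0 <- fit
  fit0$vcov <- matrix(0, 16, 16, dimnames = dimnames(fit$vcov))
  draws0 <- run_psa(perf, cfg, beta = fit0)
  v <- overall_value(standardize_table(perf), partworths_to_weights(fit))
  expect_equal(draws0$value_intervention, rep(unname(v$values[1]), 300),
               tolerance = 1e-12)
  expect_error(run_psa(perf, cfg), "exactly one")
})

test_that("swing-bootstrap weight uncertainty is supported", {
  perf <- example_perf()
  rk <- simulate_swing_rankings(table_truth(), 30, noise_sd = 0.03, seed = 6)
  cfg <- psa_config(20, seed = 8, population_size = 1000,
                    budget_grid = c(7e6, 9e6))
  draws <- run_psa(perf, cfg, swing_rankings = rk)
  expect_equal(nrow(draws), 20)
  expect_gt(stats::sd(draws$value_intervention), 0)
})

test_that("CMAC equals a brute-force recount and is monotone", {
  truth <- table_truth(ses = c(physical_functioning = 5,
                               psychological_wellbeing = 5,
                               social_participation = 0.4,
                               resilience = 0.4, enjoyment_of_life = 0.4,
                               person_centeredness = 0.4,
                               continuity_of_care = 0.4, total_costs = 500))
  perf <- simulate_trial(truth, seed = 12)
  cfg <- psa_config(2000, seed = 21, population_size = 1000,
                    budget_grid = seq(5.5e6, 9e6, length.out = 8))
  draws <- run_psa(perf, cfg, weights = example_weights("P1"))
  curve <- cmac(draws, cfg)
  # exhaustive double loop over draws x thresholds
  for (i in seq_along(cfg$budget_grid)) {
    count <- 0
    for (r in seq_len(nrow(draws))) {
      if (draws$value_intervention[r] > draws$value_comparator[r] &&
          cfg$population_size * draws$cost_intervention[r] <=
            cfg$budget_grid[i]) count <- count + 1
    }
    expect_equal(curve$probability[i], count / nrow(draws))
  }
  expect_true(all(diff(curve$probability) >= 0))
  uncond <- attr(curve, "unconditional")
  expect_true(all(curve$probability <= uncond + 1e-15))
  # below the smallest sampled impact the curve is 0; far above, it reaches
  # the unconditional preference probability
  lo <- min(cfg$population_size * draws$cost_intervention) - 1
  hi <- max(cfg$population_size * draws$cost_intervention) + 1
  cfg2 <- psa_config(2000, seed = 21, population_size = 1000,
                     budget_grid = c(lo, hi))
  curve2 <- cmac(draws, cfg2)
  expect_equal(curve2$probability[1], 0)
  expect_equal(curve2$probability[2], uncond)
})

test_that("CMAC configuration is validated", {
  expect_error(psa_config(0, 1, 10, c(1, 2)), "n_draws")
  expect_error(psa_config(10, 1, 10, c(2, 1)), "increasing")
  expect_error(psa_config(10, 1, 0, c(1, 2)), "population_size")
  d <- data.frame(value_intervention = 1, value_comparator = 0,
                  cost_intervention = 10)
  expect_error(cmac(d), "no PSA configuration")
})

test_that("CMAC curves serialize with their unconditional probability", {
  perf <- example_perf()
  cfg <- psa_config(10, seed = 4, population_size = 100,
                    budget_grid = c(5e5, 9e5))
  curve <- cmac(run_psa(perf, cfg, weights = example_weights("P1")))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cmac(curve, path)
  lines <- readLines(path)
  expect_match(lines[1], "unconditional_probability")
  back <- read.csv(text = lines[-1])
  expect_equal(back$probability, curve$probability)
})
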