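fake_trace <- function(cost, qaly, horizon = 10) {
  structure(list(totals = c(cost = cost, qaly = qaly), trace = NULL,
                 final_occupancy = NULL, strategy = "synthetic",
                 spec = list(horizon = horizon, start_age = 12,
                             discount_rate = 0.03)),
            class = "cf_trace")
}

test_that("ICERs satisfy their algebraic identities and dominance rules", {
  p <- default_params()
  uc <- run_cohort(p, "usual_care", trace = FALSE)
  tx <- run_cohort(p, "treatment", trace = FALSE)
  ic <- compute_icer(tx, uc)
  expect_identical(ic$incremental_cost, ic$cost_tx - ic$cost_uc)
  expect_identical(ic$incremental_qaly, ic$qaly_tx - ic$qaly_uc)
  expect_identical(ic$icer, ic$incremental_cost / ic$incremental_qaly)
  expect_identical(ic$dominance, "none")

  same <- compute_icer(uc, uc)
  expect_true(is.na(same$icer))
  expect_identical(same$dominance, "undefined")

  expect_identical(compute_icer(fake_trace(100, 2), fake_trace(200, 1))$dominance,
                   "dominant")
  expect_identical(compute_icer(fake_trace(300, 1), fake_trace(200, 2))$dominance,
                   "dominated")
  expect_error(compute_icer(fake_trace(1, 1, horizon = 4), fake_trace(1, 1)),
               "mismatched horizons")
})

test_that("the ICER responds monotonically to drug cost and QALY gains", {
  p <- default_params()
  icer_at_cost <- function(cost) {
    pp <- p
    pp$costs$annual_drug_cost <- cost
    uc <- run_cohort(pp, "usual_care", trace = FALSE)
    tx <- run_cohort(pp, "treatment", trace = FALSE)
    compute_icer(tx, uc)$icer
  }
  costs <- c(5e4, 1e5, 2e5, 3e5)
  icers <- vapply(costs, icer_at_cost, 0)
  expect_true(all(diff(icers) > 0))

  # linearity in the drug price: three points are collinear
  slope1 <- (icers[2] - icers[1]) / (costs[2] - costs[1])
  slope2 <- (icers[4] - icers[2]) / (costs[4] - costs[2])
  expect_equal(slope1, slope2, tolerance = 1e-9)

  # widening the utility gap raises the QALY gain and lowers the ICER
  base_icer <- compute_icer(run_cohort(p, "treatment", trace = FALSE),
                            run_cohort(p, "usual_care", trace = FALSE))
  p_gap <- param_set(p, "utility_moderate", 0.70)
  gap_icer <- compute_icer(run_cohort(p_gap, "treatment", trace = FALSE),
                           run_cohort(p_gap, "usual_care", trace = FALSE))
  expect_gt(gap_icer$incremental_qaly, base_icer$incremental_qaly)
  expect_lt(gap_icer$icer, base_icer$icer)
})

test_that("the scenario grid covers the published analysis plan", {
  grid <- default_scenario_grid()
  expect_setequal(grid$horizon[grid$label %in% paste0("base_", c(2, 4, 6, 8, 10))],
                  c(2, 4, 6, 8, 10))
  expect_true(all(c("efficacy_75", "efficacy_50", "efficacy_25",
                    "age_6", "age_25", "high_cost") %in% grid$label))

  p <- default_params()
  res <- run_scenarios(p, grid[grid$horizon == 2, ])
  expect_identical(res$label, c("base_2", "worst_2"))
  expect_true(all(res$icer > 0))
  # shorter horizons are less favourable than the 10-year base case
  res10 <- run_scenarios(p, grid[grid$label == "base_10", ])
  expect_gt(res$icer[res$label == "base_2"], res10$icer)
})

test_that("threshold search solves the fixed-point and responds to WTP", {
  p <- default_params()
  uc <- run_cohort(p, "usual_care", trace = FALSE)
  tx <- run_cohort(p, "treatment", trace = FALSE)
  base_icer <- compute_icer(tx, uc)$icer

  # fixed point: the threshold at the base-case ICER is the base drug cost
  fp <- threshold_drug_cost(p, wtp = base_icer, tolerance = 0.01)
  expect_equal(fp$threshold_cost, p$costs$annual_drug_cost, tolerance = 1e-4)
  expect_equal(fp$icer_at_threshold, base_icer, tolerance = 1e-4)

  t1 <- threshold_drug_cost(p, wtp = 150000)
  expect_equal(t1$icer_at_threshold, 150000, tolerance = 1e-3)
  t2 <- threshold_drug_cost(p, wtp = 300000)
  expect_gt(t2$threshold_cost, t1$threshold_cost)

  # infeasible when even a free drug exceeds the willingness to pay:
  # equalize state costs so longer treated survival raises non-drug costs
  p_flat <- cf_parameters(list(costs = list(
    state_cost = c(Mild = 10000, Moderate = 10000, Severe = 10000),
    pe_cost = c(Mild = 0, Moderate = 0, Severe = 0),
    transplant_cost = 0,
    post_transplant_cost_year1 = 10000, post_transplant_cost_later = 10000
  )))
  uc_f <- run_cohort(p_flat, "usual_care", trace = FALSE)
  p_free <- p_flat
  p_free$costs$annual_drug_cost <- 0
  tx_f <- run_cohort(p_free, "treatment", trace = FALSE)
  floor_icer <- compute_icer(tx_f, uc_f)$icer
  expect_gt(floor_icer, 0)
  expect_error(threshold_drug_cost(p_flat, wtp = floor_icer / 2), "infeasible")
})

test_that("tornado analysis ranks parameters by ICER spread", {
  p <- default_params()
  rng <- oneway_ranges(p)

  # a zero-width range has zero spread
  rng0 <- rng[rng$id == "utility_mild", ]
  rng0$low <- rng0$high <- rng0$base
  t0 <- tornado(p, rng0, top_k = 1)
  expect_equal(t0$spread, 0, tolerance = 1e-9)

  torn <- tornado(p, rng, top_k = 15)
  expect_identical(nrow(torn), 15L)
  expect_true(all(diff(torn$spread) <= 0))
  expect_true(all(torn$icer_low > 0) && all(torn$icer_high > 0))
  # drug price and QALY-gap drivers must rank among the top inputs
  expect_true("annual_drug_cost" %in% torn$id)

  expect_error(tornado(p, tibble::tibble(id = "nope", low = 1, high = 2)),
               "unknown parameter id")
})

test_that("PSA distributions moment-match the base-case values", {
  p <- default_params()
  dists <- psa_distributions(p)
  rng <- oneway_ranges(p)
  for (id in names(dists)) {
    base <- rng$base[rng$id == id]
    expect_lt(abs(psa_distribution_mean(dists[[id]]) - base), 1e-6)
  }
  # families follow the quantity's support
  expect_identical(dists[["pe_mild"]]$family, "beta")
  expect_identical(dists[["state_cost_mild"]]$family, "gamma")
  expect_identical(dists[["rr_pe_treatment"]]$family, "lognormal")
  expect_identical(dists[["pe_disutility"]]$family, "beta_neg")
  # calibrated schedules are not resampled
  expect_false("background_scale" %in% names(dists))

  # an impossible beta mean is a moment-matching error
  bad <- rng[rng$id == "pe_mild", ]
  bad$base <- 0
  expect_error(psa_distributions(p, bad), "moment matching failed")
})

test_that("PSA sampling is seed-deterministic and degenerates to the base case", {
  p <- default_params()
  s1 <- sample_psa(p, n = 25, seed = 9)
  s2 <- sample_psa(p, n = 25, seed = 9)
  expect_equal(as.data.frame(s1), as.data.frame(s2))
  s3 <- sample_psa(p, n = 25, seed = 10)
  expect_false(isTRUE(all.equal(s1$dcost, s3$dcost)))

  # zero-variance distributions reproduce the deterministic increments
  rng <- oneway_ranges(p)
  rng$low <- rng$high <- rng$base
  degen <- sample_psa(p, psa_distributions(p, rng), n = 1, seed = 1)
  uc <- run_cohort(p, "usual_care", trace = FALSE)
  tx <- run_cohort(p, "treatment", trace = FALSE)
  expect_equal(degen$dcost, tx$totals[["cost"]] - uc$totals[["cost"]],
               tolerance = 1e-9)
  expect_equal(degen$dqaly, tx$totals[["qaly"]] - uc$totals[["qaly"]],
               tolerance = 1e-9)
})

test_that("the acceptability curve has the right limits and monotonicity", {
  samples <- tibble::tibble(dcost = c(10, 20, 30), dqaly = c(1, 2, 3))
  expect_equal(ceac(samples, 0)$prob_cost_effective, 0)
  expect_equal(ceac(samples, 1e9)$prob_cost_effective, 1)

  p <- default_params()
  psa <- sample_psa(p, n = 100, seed = 2)
  expect_true(all(psa$dqaly > 0))
  curve <- ceac(psa, seq(0, 8e6, by = 5e5))
  expect_true(all(curve$prob_cost_effective >= 0 &
                    curve$prob_cost_effective <= 1))
  expect_true(all(diff(curve$prob_cost_effective) >= 0))

  expect_error(ceac(samples, numeric(0)), "non-empty")
  expect_error(ceac(samples[0, ], 1), "non-empty")
})

test_that("reproduce_results writes a consistent, filterable bundle", {
  p <- default_params()
  dir <- withr::local_tempdir()
  res <- reproduce_results(dir, p, horizons = 2, n_psa = 0)
  expect_identical(res$scenarios$label, c("base_2", "worst_2"))
  expect_true(file.exists(file.path(dir, "scenarios.csv")))
  expect_true(file.exists(file.path(dir, "comparison.csv")))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  # no 10-year rows requested, so no threshold stage either
  expect_null(res$threshold)
  expect_true(all(res$comparison$label %in% c("base_2", "worst_2")))
  expect_equal(res$comparison$abs_deviation,
               res$comparison$computed - res$comparison$reference)

  # deterministic stages reproduce byte-identical outputs
  dir2 <- withr::local_tempdir()
  reproduce_results(dir2, p, horizons = 2, n_psa = 0)
  strip_time <- function(f) grep("^# created", readLines(f), value = TRUE,
                                 invert = TRUE)
  expect_identical(strip_time(file.path(dir, "scenarios.csv")),
                   strip_time(file.path(dir2, "scenarios.csv")))
})
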