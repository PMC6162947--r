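test_that("discounting follows the standard present-value form", {
  expect_identical(discount(500, 0.03, 0), 500)
  expect_equal(discount(103, 0.03, 1), 100)
  expect_identical(discount(77, 0, 9), 77)
  expect_equal(discount(100, 0.05, 3), 100 / 1.05^3)
})

test_that("cycle models encode the strategy-specific dynamics", {
  p <- default_params()
  tr <- p$transitions

  uc <- build_cycle_model(p, "usual_care", cycle_index = 3)
  expect_equal(uc$pe, tr$pe)
  expect_false(uc$improving)
  expect_equal(uc$progress_with_pe, tr$progress_with_pe)

  # full efficacy: constant relative risk, no progression after year 0
  tx1 <- build_cycle_model(p, "treatment", efficacy_fraction = 1, cycle_index = 3)
  expect_equal(tx1$pe, tr$pe * 0.74)
  expect_true(all(tx1$progress_with_pe == 0))
  expect_true(all(tx1$progress_no_pe == 0))
  expect_false(tx1$improving)

  # zero efficacy from year 1: identical to usual care
  tx0 <- build_cycle_model(p, "treatment", efficacy_fraction = 0, cycle_index = 3)
  expect_equal(tx0$pe, tr$pe)
  expect_equal(tx0$progress_with_pe, tr$progress_with_pe)
  expect_false(tx0$improving)

  # half efficacy: progression at half the usual-care values, blended risk
  tx5 <- build_cycle_model(p, "treatment", efficacy_fraction = 0.5, cycle_index = 3)
  expect_equal(tx5$progress_with_pe, tr$progress_with_pe / 2)
  expect_equal(unname(tx5$pe / tr$pe), rep(1 - 0.5 * (1 - 0.74), 3))

  # cycle 0 treatment: full trial effect and improvement branches
  tx_first <- build_cycle_model(p, "treatment", efficacy_fraction = 0, cycle_index = 0)
  expect_true(tx_first$improving)
  expect_equal(tx_first$pe, tr$pe * 0.74)
  expect_true(all(tx_first$progress_with_pe == 0))
})

test_that("every conditional branch distribution sums to one", {
  p <- default_params()
  for (strategy in c("usual_care", "treatment")) {
    for (cyc in c(0, 1, 5)) {
      m <- build_cycle_model(p, strategy, efficacy_fraction = 0.35,
                             cycle_index = cyc)
      br <- cycle_branches(m)
      sums <- rowSums(br[, c("Mild", "Moderate", "Severe", "NewTransplant", "Dead")])
      expect_true(all(abs(sums - 1) < 1e-12))
      # no transplant branch leaves mild or moderate
      expect_true(all(br$NewTransplant[br$state != "Severe"] == 0))
    }
  }
})

test_that("markov_step conserves mass, keeps death absorbing and reports incidences", {
  p <- default_params()
  m <- build_cycle_model(p, "usual_care", cycle_index = 2)

  dead_only <- setNames(c(0, 0, 0, 0, 1), cf_states())
  out <- markov_step(dead_only, m)
  expect_equal(unname(out$occupancy[["Dead"]]), 1)
  expect_equal(sum(out$occupancy), 1)

  # exacerbations only: occupancy is unchanged, incidence equals PE probability
  pe_only <- inert_params(list(transitions = list(
    pe = c(Mild = 0.3, Moderate = 0.5, Severe = 0.7)
  )))
  m2 <- build_cycle_model(pe_only, "usual_care", cycle_index = 0)
  occ <- setNames(c(0.5, 0.3, 0.2, 0, 0), cf_states())
  out2 <- markov_step(occ, m2)
  expect_equal(out2$occupancy[cf_states()], occ[cf_states()])
  expect_equal(unname(out2$incidences$pe), c(0.5 * 0.3, 0.3 * 0.5, 0.2 * 0.7))

  # property: random occupancies stay conserved with non-decreasing death
  set.seed(20)
  for (i in 1:25) {
    w <- runif(5)
    occ <- setNames(w / sum(w), cf_states())
    attr(occ, "pt") <- c(0.4, 0.6) * occ[["PostTransplant"]]
    strategy <- sample(c("usual_care", "treatment"), 1)
    mm <- build_cycle_model(p, strategy, efficacy_fraction = runif(1),
                            cycle_index = sample(0:9, 1))
    nxt <- markov_step(occ, mm)$occupancy
    expect_lt(abs(sum(nxt) - 1), 1e-9)
    expect_gte(nxt[["Dead"]], occ[["Dead"]])
  }

  expect_error(markov_step(setNames(c(0.5, 0.2, 0.1, 0.1, 0.2), cf_states()), m),
               "sum to 1")
})

test_that("single-state accrual matches the registry cost and utility entries", {
  p <- default_params()
  all_mild <- setNames(c(1, 0, 0, 0, 0), cf_states())
  no_events <- list(pe = c(Mild = 0, Moderate = 0, Severe = 0), transplants = 0)

  acc <- accrue_cycle(all_mild, no_events, p, "usual_care", cycle_index = 0)
  expect_equal(unname(acc["cost"]), 7566.91)
  expect_equal(unname(acc["qaly"]), 0.86)

  # certain exacerbation: utility drops by the exacerbation disutility
  pe_all <- list(pe = c(Mild = 1, Moderate = 0, Severe = 0), transplants = 0)
  acc2 <- accrue_cycle(all_mild, pe_all, p, "usual_care", cycle_index = 0)
  expect_equal(unname(acc2["qaly"]), 0.86 - 0.17)
  expect_equal(unname(acc2["cost"]), 7566.91 + 2575.97)

  # zero costs give zero cost regardless of occupancy
  p0 <- plain_params(list(costs = list(
    annual_drug_cost = 0,
    state_cost = c(Mild = 0, Moderate = 0, Severe = 0),
    pe_cost = c(Mild = 0, Moderate = 0, Severe = 0),
    transplant_cost = 0, post_transplant_cost_year1 = 0,
    post_transplant_cost_later = 0
  )))
  acc3 <- accrue_cycle(all_mild, pe_all, p0, "treatment", cycle_index = 0)
  expect_identical(unname(acc3["cost"]), 0)
})

test_that("run_cohort traces conserve mass with monotone mortality", {
  p <- default_params()
  for (strategy in c("usual_care", "treatment")) {
    res <- run_cohort(p, strategy)
    tr <- res$trace
    occ <- as.matrix(tr[, cf_states()])
    expect_true(all(abs(rowSums(occ) - 1) < 1e-9))
    expect_true(all(diff(tr$Dead) >= -1e-12))
    expect_true(all(is.finite(tr$cost)) && all(tr$cost >= 0))
    expect_true(all(is.finite(tr$qaly)) && all(tr$qaly >= 0))
    expect_equal(sum(tr$cost), res$totals[["cost"]])
    expect_equal(sum(tr$qaly), res$totals[["qaly"]])
  }

  empty <- run_cohort(p, "usual_care", spec = list(horizon = 0))
  expect_equal(unname(empty$totals), c(0, 0))
  expect_equal(nrow(empty$trace), 0)
})

test_that("treatment QALYs are monotone in long-term effectiveness", {
  p <- default_params()
  qalys <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(e) {
    run_cohort(p, "treatment", spec = list(efficacy_fraction = e),
               trace = FALSE)$totals[["qaly"]]
  }, 0)
  expect_true(all(diff(qalys) > 0))
})

test_that("a neutralized treatment arm recovers the usual-care trace exactly", {
  # the treatment arm always gets the full first-year effect, so recovering
  # usual care exactly requires neutral first-year dynamics too: relative
  # risk 1, improvement off, and no progression in either arm
  p <- cf_parameters(list(
    transitions = list(
      rr_pe_treatment = 1,
      progress_with_pe = c(MildToModerate = 0, ModerateToSevere = 0),
      progress_no_pe = c(MildToModerate = 0, ModerateToSevere = 0),
      improve_with_pe = c(ModerateToMild = 0, SevereToModerate = 0),
      improve_no_pe = c(ModerateToMild = 0, SevereToModerate = 0)
    ),
    costs = list(annual_drug_cost = 0),
    cohort = list(efficacy_fraction = 0)
  ))
  uc <- run_cohort(p, "usual_care")
  tx <- run_cohort(p, "treatment")
  expect_equal(tx$totals, uc$totals, tolerance = 1e-12)
  expect_equal(tx$trace[, -1], uc$trace[, -1], tolerance = 1e-12)
})

test_that("constant cohorts give the closed-form QALY total", {
  # no mortality, no events, no discounting: occupancy is constant, so the
  # QALY total is the number of accrual stages times the mean utility
  p <- inert_params()
  ubar <- sum(p$cohort$start_distribution *
                p$utilities$state_utility[disease_states()])
  res <- run_cohort(p, "usual_care", spec = list(horizon = 6))
  expect_equal(res$totals[["qaly"]], (6 + 1) * ubar, tolerance = 1e-12)

  p_plain <- p
  p_plain$options$terminal_accrual <- FALSE
  res2 <- run_cohort(p_plain, "usual_care", spec = list(horizon = 6))
  expect_equal(res2$totals[["qaly"]], 6 * ubar, tolerance = 1e-12)

  # half-cycle correction removes half a stage at each end
  p_hcc <- p
  p_hcc$options$half_cycle_correction <- TRUE
  res3 <- run_cohort(p_hcc, "usual_care", spec = list(horizon = 6))
  expect_equal(res3$totals[["qaly"]], 6 * ubar, tolerance = 1e-12)
})

test_that("short-horizon traces match exhaustive path enumeration", {
  p <- default_params()
  for (strategy in c("usual_care", "treatment")) {
    for (e in c(1, 0.4)) {
      pp <- p
      pp$cohort$efficacy_fraction <- e
      for (h in 1:3) {
        res <- run_cohort(pp, strategy, spec = list(horizon = h), trace = FALSE)
        oracle <- oracle_run(pp, strategy, h)
        expect_equal(res$totals[["cost"]], oracle$cost, tolerance = 1e-10)
        expect_equal(res$totals[["qaly"]], oracle$qaly, tolerance = 1e-10)
        expect_equal(unname(res$final_occupancy[cf_states()]),
                     unname(oracle$final[cf_states()]), tolerance = 1e-10)
      }
    }
  }
})
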