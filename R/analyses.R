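# ---------------------------------------------------------------------------
# Analyses on top of cohort traces: ICERs, scenario grid, threshold price,
# one-way (tornado) sensitivity analysis.
# ---------------------------------------------------------------------------

#' Incremental cost-effectiveness ratio of treatment vs usual care
#'
#' Computes incremental cost, incremental QALYs and their ratio from two
#' cohort traces that share every cohort setting except the strategy.
#' Dominance follows the standard cost-effectiveness quadrant conventions:
#' a cheaper, at-least-as-effective treatment is `dominant`; a costlier,
#' no-more-effective one is `dominated`; a zero QALY difference leaves the
#' ratio `undefined`.
#'
#' @param trace_tx Treatment-arm trace from [run_cohort()].
#' @param trace_uc Usual-care trace from [run_cohort()].
#' @return Object of class `cf_icer`: list with `cost_uc`, `cost_tx`,
#'   `qaly_uc`, `qaly_tx`, `incremental_cost`, `incremental_qaly`, `icer`
#'   (`NA` when undefined) and `dominance`
#'   (`"none"`, `"dominant"`, `"dominated"` or `"undefined"`).
#' @export
compute_icer <- function(trace_tx, trace_uc) {
  stopifnot(inherits(trace_tx, "cf_trace"), inherits(trace_uc, "cf_trace"))
  if (trace_tx$spec$horizon != trace_uc$spec$horizon) {
    stop("traces have mismatched horizons (", trace_tx$spec$horizon, " vs ",
         trace_uc$spec$horizon, ")", call. = FALSE)
  }
  for (field in c("start_age", "discount_rate")) {
    if (!isTRUE(all.equal(trace_tx$spec[[field]], trace_uc$spec[[field]]))) {
      stop("traces have mismatched cohort spec field '", field, "'",
           call. = FALSE)
    }
  }
  d_cost <- trace_tx$totals[["cost"]] - trace_uc$totals[["cost"]]
  d_qaly <- trace_tx$totals[["qaly"]] - trace_uc$totals[["qaly"]]
  dominance <- "none"
  if (d_qaly == 0) {
    dominance <- if (d_cost == 0) "undefined" else
      if (d_cost < 0) "dominant" else "dominated"
  } else if (d_cost <= 0 && d_qaly > 0) {
    dominance <- "dominant"
  } else if (d_cost >= 0 && d_qaly < 0) {
    dominance <- "dominated"
  }
  structure(list(
    cost_uc = trace_uc$totals[["cost"]],
    cost_tx = trace_tx$totals[["cost"]],
    qaly_uc = trace_uc$totals[["qaly"]],
    qaly_tx = trace_tx$totals[["qaly"]],
    incremental_cost = d_cost,
    incremental_qaly = d_qaly,
    icer = if (d_qaly != 0) d_cost / d_qaly else NA_real_,
    dominance = dominance
  ), class = "cf_icer")
}

#' @export
print.cf_icer <- function(x, ...) {
  cat("<cf_icer>\n")
  cat(sprintf("  usual care: $%s, %.3f QALYs\n",
              format(round(x$cost_uc), big.mark = ","), x$qaly_uc))
  cat(sprintf("  treatment : $%s, %.3f QALYs\n",
              format(round(x$cost_tx), big.mark = ","), x$qaly_tx))
  cat(sprintf("  incremental: $%s / %.3f QALYs",
              format(round(x$incremental_cost), big.mark = ","),
              x$incremental_qaly))
  if (!is.na(x$icer)) {
    cat(sprintf(" -> ICER $%s per QALY", format(round(x$icer), big.mark = ",")))
  }
  if (x$dominance != "none") cat(sprintf("  [%s]", x$dominance))
  cat("\n")
  invisible(x)
}

# run both arms under a scenario-adjusted parameter set and return the ICER
.icer_for <- function(params, spec = NULL) {
  uc <- run_cohort(params, "usual_care", spec = spec, trace = FALSE)
  tx <- run_cohort(params, "treatment", spec = spec, trace = FALSE)
  compute_icer(tx, uc)
}

#' Default scenario grid
#'
#' The packaged grid of deterministic scenarios: base-case (100% long-term
#' effectiveness) and worst-case (0%) at horizons 2, 4, 6, 8 and 10 years;
#' intermediate long-term effectiveness 75/50/25% at 10 years; starting ages
#' 6 and 25 with their registry severity splits; and the high-cost scenario.
#'
#' @return A tibble with columns `label`, `horizon`, `start_age`,
#'   `efficacy_fraction`, `cost_scenario`.
#' @export
default_scenario_grid <- function() {
  base <- tibble::tibble(
    label = c(outer(c("base", "worst"), c(2, 4, 6, 8, 10), paste, sep = "_")),
    horizon = rep(c(2, 4, 6, 8, 10), each = 2),
    start_age = 12,
    efficacy_fraction = rep(c(1, 0), 5),
    cost_scenario = "base"
  )
  extra <- tibble::tibble(
    label = c("efficacy_75", "efficacy_50", "efficacy_25",
              "age_6", "age_25", "high_cost"),
    horizon = 10,
    start_age = c(12, 12, 12, 6, 25, 12),
    efficacy_fraction = c(0.75, 0.5, 0.25, 1, 1, 1),
    cost_scenario = c("base", "base", "base", "base", "base", "high_cost")
  )
  rbind(base, extra)
}

#' Run a grid of deterministic scenarios
#'
#' Each scenario row adjusts the horizon, starting age (with its registry
#' severity split), long-term effectiveness fraction and cost scenario, runs
#' both strategy arms, and reports the incremental results.
#'
#' @param params A [cf_parameters()] object.
#' @param specs Scenario grid as returned by [default_scenario_grid()] (the
#'   default), or any data frame with the same columns.
#' @return A tibble: the scenario columns plus `cost_uc`, `qaly_uc`,
#'   `cost_tx`, `qaly_tx`, `incremental_cost`, `incremental_qaly`, `icer`,
#'   `dominance`.
#' @export
run_scenarios <- function(params, specs = default_scenario_grid()) {
  needed <- c("label", "horizon", "start_age", "efficacy_fraction", "cost_scenario")
  if (!all(needed %in% names(specs))) {
    stop("scenario grid must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  out <- vector("list", nrow(specs))
  for (i in seq_len(nrow(specs))) {
    row <- specs[i, ]
    p <- apply_cost_scenario(params, row$cost_scenario)
    spec <- list(
      horizon = row$horizon,
      start_age = row$start_age,
      start_distribution = age_start_distribution(row$start_age),
      efficacy_fraction = row$efficacy_fraction
    )
    ic <- .icer_for(p, spec)
    out[[i]] <- tibble::tibble(
      label = row$label, horizon = row$horizon, start_age = row$start_age,
      efficacy_fraction = row$efficacy_fraction,
      cost_scenario = row$cost_scenario,
      cost_uc = ic$cost_uc, qaly_uc = ic$qaly_uc,
      cost_tx = ic$cost_tx, qaly_tx = ic$qaly_tx,
      incremental_cost = ic$incremental_cost,
      incremental_qaly = ic$incremental_qaly,
      icer = ic$icer, dominance = ic$dominance
    )
  }
  do.call(rbind, out)
}

#' Threshold annual drug cost at a willingness-to-pay level
#'
#' Finds the annual drug cost at which the treatment's ICER equals the
#' willingness-to-pay threshold, by bisection. Incremental QALYs do not
#' depend on the drug price and incremental cost is strictly increasing in
#' it, so the root is unique; if even a free drug exceeds the threshold the
#' search is flagged infeasible.
#'
#' @param params A [cf_parameters()] object.
#' @param wtp Willingness-to-pay threshold in USD per QALY (> 0); default
#'   the registry value (150,000).
#' @param tolerance Bisection interval width at termination, in USD.
#' @param spec Optional cohort overrides as in [run_cohort()].
#' @return List with `threshold_cost` (USD per year), `icer_at_threshold`,
#'   `iterations`.
#' @export
threshold_drug_cost <- function(params, wtp = params$cohort$wtp,
                                tolerance = 0.01, spec = NULL) {
  stopifnot(wtp > 0, tolerance > 0)
  uc <- run_cohort(params, "usual_care", spec = spec, trace = FALSE)
  icer_at <- function(cost) {
    p <- params
    p$costs$annual_drug_cost <- cost
    tx <- run_cohort(p, "treatment", spec = spec, trace = FALSE)
    ic <- compute_icer(tx, uc)
    if (ic$incremental_qaly <= 0) {
      stop("treatment gains no QALYs under this spec; threshold undefined",
           call. = FALSE)
    }
    ic$icer
  }
  lo <- 0
  if (icer_at(lo) > wtp) {
    stop("infeasible: the ICER at zero drug cost (",
         format(round(icer_at(lo)), big.mark = ","),
         ") already exceeds the willingness-to-pay threshold", call. = FALSE)
  }
  hi <- params$costs$annual_drug_cost
  if (hi <= 0) hi <- 1
  while (icer_at(hi) < wtp) hi <- hi * 2
  it <- 0
  while (hi - lo > tolerance) {
    mid <- (lo + hi) / 2
    if (icer_at(mid) < wtp) lo <- mid else hi <- mid
    it <- it + 1
  }
  root <- (lo + hi) / 2
  list(threshold_cost = root, icer_at_threshold = icer_at(root), iterations = it)
}

#' One-way (tornado) sensitivity analysis
#'
#' Re-computes the base-case ICER with each registered parameter set to its
#' low and high bound in turn, all other parameters at base case, and ranks
#' parameters by the width of the induced ICER interval.
#'
#' @param params A [cf_parameters()] object.
#' @param ranges Range table as returned by [oneway_ranges()] (columns `id`,
#'   `low`, `high`).
#' @param top_k Number of parameters to keep, by decreasing spread
#'   (default 15).
#' @param spec Optional cohort overrides as in [run_cohort()].
#' @return A tibble ordered by decreasing `spread`, with columns `id`,
#'   `low`, `high`, `icer_low`, `icer_high`, `spread` and the base-case
#'   `icer_base` as an attribute.
#' @export
tornado <- function(params, ranges = oneway_ranges(params), top_k = 15,
                    spec = NULL) {
  if (!all(c("id", "low", "high") %in% names(ranges))) {
    stop("ranges must have columns id, low, high", call. = FALSE)
  }
  icer_base <- .icer_for(params, spec)$icer
  n <- nrow(ranges)
  icer_low <- icer_high <- numeric(n)
  for (i in seq_len(n)) {
    icer_low[i] <- .icer_for(param_set(params, ranges$id[i], ranges$low[i]), spec)$icer
    icer_high[i] <- .icer_for(param_set(params, ranges$id[i], ranges$high[i]), spec)$icer
  }
  out <- tibble::tibble(
    id = ranges$id, low = ranges$low, high = ranges$high,
    icer_low = icer_low, icer_high = icer_high,
    spread = abs(icer_high - icer_low)
  )
  out <- out[order(-out$spread), ]
  out <- utils::head(out, top_k)
  attr(out, "icer_base") <- icer_base
  out
}
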