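# ---------------------------------------------------------------------------
# Deterministic cohort state-transition engine.
#
# Within each 1-year cycle the event tree is applied in a fixed order,
# identically in both strategy arms:
#   1. pulmonary exacerbation (PE) draw in each live disease state;
#   2. PE-conditional death;
#   3. lung transplant among severe survivors (same probability with and
#      without PE), with transplant-year mortality charged immediately;
#   4. disease progression (usual care / residual-efficacy treatment) or
#      improvement (treatment, first cycle only) among the remainder;
#   5. background CF mortality as a competing risk on all still-alive
#      disease-state occupants. Post-transplant occupants face only the
#      year-since-transplant mortality schedule.
# ---------------------------------------------------------------------------

#' Discount a value to present terms
#'
#' Cycle 0 is undiscounted; a value accrued in cycle `t` is divided by
#' `(1 + rate)^t`.
#'
#' @param value Numeric value(s) to discount.
#' @param rate Annual discount rate (>= 0); the model default is 0.03.
#' @param cycle_index Zero-based cycle index.
#' @return Discounted value.
#' @export
#' @examples
#' discount(103, 0.03, 1)  # 100
discount <- function(value, rate, cycle_index) {
  stopifnot(rate >= 0, all(cycle_index >= 0))
  value / (1 + rate)^cycle_index
}

#' Build the one-cycle transition model for a strategy
#'
#' Resolves the per-state branch probabilities of the cycle event tree for
#' one strategy, cycle and age. Usual care uses the registry probabilities
#' with no improvement branches. The treatment arm applies the full trial
#' effect in cycle 0 (PE probability scaled by the relative risk, no
#' progression, improvement transitions active) and from cycle 1 onward
#' blends linearly between usual-care dynamics (efficacy 0) and maintained
#' benefit (efficacy 1): progression is scaled by `1 - e` and the effective
#' relative risk is `1 - e * (1 - rr)`. Treatment effects do not apply in the
#' post-transplant state (therapy is stopped at transplant).
#'
#' @param params A [cf_parameters()] object.
#' @param strategy `"usual_care"` or `"treatment"`.
#' @param efficacy_fraction Long-term effectiveness `e` in \[0, 1\].
#' @param cycle_index Zero-based cycle index.
#' @param age Cohort age (years) at the start of the cycle.
#' @return An object of class `cf_cycle_model`.
#' @export
build_cycle_model <- function(params, strategy = c("usual_care", "treatment"),
                              efficacy_fraction = params$cohort$efficacy_fraction,
                              cycle_index = 0,
                              age = params$cohort$start_age + cycle_index) {
  strategy <- match.arg(strategy)
  e <- efficacy_fraction
  stopifnot(e >= 0, e <= 1, cycle_index >= 0)
  tr <- params$transitions
  treated <- strategy == "treatment"

  rr_eff <- if (!treated) 1 else if (cycle_index == 0) tr$rr_pe_treatment else
    1 - e * (1 - tr$rr_pe_treatment)
  prog_scale <- if (!treated) 1 else if (cycle_index == 0) 0 else (1 - e)
  improving <- treated && cycle_index == 0

  pe <- tr$pe * rr_eff
  if (any(pe < 0 | pe > 1)) {
    stop("effective PE probabilities leave [0, 1] after applying the relative risk",
         call. = FALSE)
  }
  prog_with_pe <- tr$progress_with_pe * prog_scale
  prog_no_pe <- tr$progress_no_pe * prog_scale

  age_idx <- min(max(round(age), 0), length(tr$background_mortality) - 1)
  q_bg <- tr$background_mortality[age_idx + 1] * tr$background_scale
  .check_prob(q_bg, "background mortality at current age")

  structure(list(
    strategy = strategy,
    cycle_index = cycle_index,
    age = age,
    efficacy_fraction = e,
    pe = pe,
    death_given_pe = tr$death_given_pe,
    transplant_given_severe = tr$transplant_given_severe,
    transplant_year_death = tr$transplant_year_death,
    progress_with_pe = prog_with_pe,
    progress_no_pe = prog_no_pe,
    improving = improving,
    improve_with_pe = tr$improve_with_pe,
    improve_no_pe = tr$improve_no_pe,
    background_mortality = q_bg,
    post_transplant_mortality = tr$post_transplant_mortality
  ), class = "cf_cycle_model")
}

#' Expand a cycle model into explicit branch distributions
#'
#' For each live disease state and exacerbation stratum, returns the full
#' conditional outcome distribution over destination states (including the
#' newly transplanted and dead). Every row sums to one: the event tree is
#' exhaustive by construction, so this expansion is the object checked by the
#' conservation invariants.
#'
#' @param model A `cf_cycle_model`.
#' @return A tibble with columns `state`, `stratum` (`pe` / `no_pe`) and one
#'   column per destination (`Mild`, `Moderate`, `Severe`, `NewTransplant`,
#'   `Dead`).
#' @export
cycle_branches <- function(model) {
  stopifnot(inherits(model, "cf_cycle_model"))
  dest <- c("Mild", "Moderate", "Severe", "NewTransplant", "Dead")
  rows <- list()
  for (s in disease_states()) {
    for (stratum in c("pe", "no_pe")) {
      p <- setNames(numeric(5), dest)
      alive <- 1
      if (stratum == "pe") {
        p["Dead"] <- p["Dead"] + model$death_given_pe[s]
        alive <- alive - model$death_given_pe[s]
      }
      if (s == "Severe") {
        tx <- alive * model$transplant_given_severe
        p["Dead"] <- p["Dead"] + tx * model$transplant_year_death
        p["NewTransplant"] <- tx * (1 - model$transplant_year_death)
        alive <- alive - tx
      }
      move <- 0
      to <- s
      if (model$improving) {
        imp <- if (stratum == "pe") model$improve_with_pe else model$improve_no_pe
        if (s == "Moderate") { move <- alive * imp[["ModerateToMild"]]; to <- "Mild" }
        if (s == "Severe")   { move <- alive * imp[["SevereToModerate"]]; to <- "Moderate" }
      } else {
        pr <- if (stratum == "pe") model$progress_with_pe else model$progress_no_pe
        if (s == "Mild")     { move <- alive * pr[["MildToModerate"]]; to <- "Moderate" }
        if (s == "Moderate") { move <- alive * pr[["ModerateToSevere"]]; to <- "Severe" }
      }
      p[to] <- p[to] + move
      p[s] <- p[s] + alive - move
      # background mortality competes on disease-state survivors only
      q <- model$background_mortality
      live <- c("Mild", "Moderate", "Severe")
      p["Dead"] <- p["Dead"] + sum(p[live]) * q
      p[live] <- p[live] * (1 - q)
      rows[[length(rows) + 1]] <- tibble::as_tibble(
        c(list(state = s, stratum = stratum), as.list(p))
      )
    }
  }
  do.call(rbind, rows)
}

# internal occupancy layout: named numeric c(Mild, Moderate, Severe, Dead)
# plus a post-transplant tunnel vector pt[j] = fraction j years past transplant

#' Advance the cohort by one cycle
#'
#' Applies the cycle event tree to an occupancy vector over the five model
#' states and returns the next occupancy together with the within-cycle event
#' incidences (exacerbations per state, transplants, deaths). Mass is
#' conserved to numerical precision and the dead fraction never decreases.
#'
#' Post-transplant occupancy carries a years-since-transplant breakdown in
#' attribute `pt`; if absent, all post-transplant mass is treated as beyond
#' the first post-transplant year.
#'
#' @param occupancy Named numeric vector over [cf_states()] summing to 1,
#'   optionally with attribute `pt`.
#' @param model A `cf_cycle_model` from [build_cycle_model()].
#' @return List with `occupancy` (next cycle, same layout) and `incidences`
#'   (named list: `pe` per disease state, `transplants`, `deaths`).
#' @export
markov_step <- function(occupancy, model) {
  stopifnot(inherits(model, "cf_cycle_model"))
  occ <- occupancy[cf_states()]
  if (any(is.na(occ)) || any(occ < -1e-12)) {
    stop("occupancy must be a non-negative vector over the five model states",
         call. = FALSE)
  }
  if (abs(sum(occ) - 1) > 1e-9) {
    stop("occupancy must sum to 1 (got ", format(sum(occ), digits = 12), ")",
         call. = FALSE)
  }
  pt <- attr(occupancy, "pt")
  if (is.null(pt)) pt <- c(0, occ[["PostTransplant"]])
  if (abs(sum(pt) - occ[["PostTransplant"]]) > 1e-9) {
    stop("post-transplant breakdown does not match PostTransplant occupancy",
         call. = FALSE)
  }
  st <- .engine_step(
    o = occ[disease_states()], pt = pt, dead = occ[["Dead"]], model = model
  )
  out <- c(st$o, PostTransplant = sum(st$pt), Dead = st$dead)
  names(out) <- cf_states()
  attr(out, "pt") <- st$pt
  list(occupancy = out, incidences = st$incidences)
}

# core one-cycle update shared by markov_step() and the trace runner
.engine_step <- function(o, pt, dead, model) {
  pe <- model$pe
  d_pe <- model$death_given_pe
  pe_inc <- o * pe
  new <- c(Mild = 0, Moderate = 0, Severe = 0)
  d_new <- 0
  pt_new <- 0
  tx_inc <- 0
  for (s in disease_states()) {
    for (stratum in c("pe", "no_pe")) {
      frac <- if (stratum == "pe") o[[s]] * pe[[s]] else o[[s]] * (1 - pe[[s]])
      if (frac == 0) next
      if (stratum == "pe") {
        d_new <- d_new + frac * d_pe[[s]]
        frac <- frac * (1 - d_pe[[s]])
      }
      if (s == "Severe") {
        txf <- frac * model$transplant_given_severe
        tx_inc <- tx_inc + txf
        d_new <- d_new + txf * model$transplant_year_death
        pt_new <- pt_new + txf * (1 - model$transplant_year_death)
        frac <- frac - txf
      }
      move <- 0
      to <- s
      if (model$improving) {
        imp <- if (stratum == "pe") model$improve_with_pe else model$improve_no_pe
        if (s == "Moderate") { move <- frac * imp[["ModerateToMild"]]; to <- "Mild" }
        if (s == "Severe")   { move <- frac * imp[["SevereToModerate"]]; to <- "Moderate" }
      } else {
        pr <- if (stratum == "pe") model$progress_with_pe else model$progress_no_pe
        if (s == "Mild")     { move <- frac * pr[["MildToModerate"]]; to <- "Moderate" }
        if (s == "Moderate") { move <- frac * pr[["ModerateToSevere"]]; to <- "Severe" }
      }
      new[[to]] <- new[[to]] + move
      new[[s]] <- new[[s]] + frac - move
    }
  }
  q <- model$background_mortality
  d_new <- d_new + sum(new) * q
  new <- new * (1 - q)
  # post-transplant tunnel: element j of the schedule applies j years after
  # the transplant year (schedule element 1, the transplant year itself, is
  # charged at transition time above)
  ptm_tail <- model$post_transplant_mortality[-1]
  if (length(pt)) {
    ptm <- c(ptm_tail, rep(tail(ptm_tail, 1), length(pt)))[seq_along(pt)]
    d_new <- d_new + sum(pt * ptm)
    pt_surv <- pt * (1 - ptm)
    n <- length(pt_surv)
    # last element accumulates so the tunnel never sheds mass
    pt <- if (n == 1) c(pt_new, pt_surv) else
      c(pt_new, pt_surv[seq_len(n - 2)], pt_surv[n - 1] + pt_surv[n])
  } else {
    pt <- pt_new
  }
  dead <- dead + d_new
  list(
    o = new, pt = pt, dead = dead,
    incidences = list(pe = pe_inc, transplants = tx_inc, deaths = d_new)
  )
}

#' Accrue one cycle's discounted cost and QALYs
#'
#' State rewards (annual state costs and utilities, drug cost in the
#' treatment arm) accrue on the start-of-cycle occupancy; event rewards
#' (exacerbation cost and disutility, one-time transplant cost) accrue on the
#' cycle's event incidences. The first post-transplant year carries the
#' higher year-one cost. Drug cost is charged to every treated, alive,
#' non-post-transplant occupant for the full cycle. Both streams are
#' discounted with [discount()].
#'
#' @param occupancy Start-of-cycle occupancy (layout as in [markov_step()]).
#' @param incidences Event incidences as returned by [markov_step()]; may be
#'   `NULL` for a terminal state-reward-only accrual.
#' @param params A [cf_parameters()] object.
#' @param strategy `"usual_care"` or `"treatment"`.
#' @param cycle_index Zero-based cycle index used for discounting.
#' @return Named numeric vector `c(cost, qaly)` (discounted).
#' @export
accrue_cycle <- function(occupancy, incidences, params,
                         strategy = c("usual_care", "treatment"),
                         cycle_index = 0) {
  strategy <- match.arg(strategy)
  occ <- occupancy[cf_states()]
  pt <- attr(occupancy, "pt")
  if (is.null(pt)) pt <- c(0, occ[["PostTransplant"]])
  co <- params$costs
  ut <- params$utilities
  live <- occ[disease_states()]

  cost <- sum(live * co$state_cost[disease_states()]) +
    pt[1] * co$post_transplant_cost_year1 +
    sum(pt[-1]) * co$post_transplant_cost_later
  if (strategy == "treatment") cost <- cost + sum(live) * co$annual_drug_cost
  qaly <- sum(live * ut$state_utility[disease_states()]) +
    sum(pt) * ut$state_utility[["PostTransplant"]]

  if (!is.null(incidences)) {
    cost <- cost + sum(incidences$pe * co$pe_cost[disease_states()]) * co$pe_weight +
      incidences$transplants * co$transplant_cost
    qaly <- qaly + sum(incidences$pe) * ut$pe_disutility
  }
  if (cost < 0 || qaly < 0) {
    stop("negative cycle accrual; check cost and utility inputs", call. = FALSE)
  }
  rate <- params$cohort$discount_rate
  c(cost = discount(cost, rate, cycle_index),
    qaly = discount(qaly, rate, cycle_index))
}

#' Run the cohort model for one strategy
#'
#' Propagates the starting severity distribution through the cycle event tree
#' for `horizon` annual cycles, accruing discounted costs and QALYs. State
#' rewards are accrued at stages `0..horizon` inclusive (the terminal stage
#' carries state rewards but no transition events); event rewards accrue at
#' each of the `horizon` transitions. Set `options$terminal_accrual` to
#' `FALSE` for accrual at stages `0..horizon-1` only, and
#' `options$half_cycle_correction` to `TRUE` to half-weight the first and
#' terminal stage state rewards.
#'
#' @param params A [cf_parameters()] object.
#' @param strategy `"usual_care"` or `"treatment"`.
#' @param spec Optional named list overriding cohort settings for this run
#'   (any of `start_age`, `start_distribution`, `horizon`, `discount_rate`,
#'   `efficacy_fraction`).
#' @param trace Keep the full per-cycle trace (default `TRUE`); `FALSE`
#'   returns totals only and is used by the sensitivity-analysis loops.
#' @return An object of class `cf_trace`: list with `totals` (named vector
#'   `cost`, `qaly`), `trace` (tibble: one row per stage with occupancy,
#'   incidences and discounted streams; `NULL` when `trace = FALSE`),
#'   `final_occupancy`, `strategy` and the resolved `spec`.
#' @export
#' @examples
#' p <- cf_parameters()
#' uc <- run_cohort(p, "usual_care")
#' uc$totals
run_cohort <- function(params, strategy = c("usual_care", "treatment"),
                       spec = NULL, trace = TRUE) {
  strategy <- match.arg(strategy)
  cohort <- params$cohort
  if (!is.null(spec)) {
    bad <- setdiff(names(spec), names(cohort))
    if (length(bad)) {
      stop("unknown cohort spec field(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    cohort[names(spec)] <- spec
  }
  sd_ <- cohort$start_distribution[disease_states()]
  if (abs(sum(sd_) - 1) > 1e-8) {
    stop("start_distribution must sum to 1", call. = FALSE)
  }
  horizon <- cohort$horizon
  e <- cohort$efficacy_fraction
  run_params <- params
  run_params$cohort <- cohort

  o <- sd_
  pt <- numeric(max(horizon, 1) + 1)
  dead <- 0
  tot <- c(cost = 0, qaly = 0)
  opts <- params$options
  n_stage <- if (opts$terminal_accrual) horizon + 1 else horizon
  rows <- if (trace) vector("list", max(n_stage, 1)) else NULL

  if (horizon == 0) {
    out <- list(
      totals = c(cost = 0, qaly = 0),
      trace = if (trace) .trace_row(NULL) else NULL,
      final_occupancy = .occ_vector(o, pt, dead),
      strategy = strategy, spec = cohort
    )
    class(out) <- "cf_trace"
    return(out)
  }

  for (t in 0:(horizon - 1)) {
    model <- build_cycle_model(run_params, strategy, e, t, cohort$start_age + t)
    occ_vec <- .occ_vector(o, pt, dead)
    st <- .engine_step(o, pt, dead, model)
    acc <- accrue_cycle(occ_vec, st$incidences, run_params, strategy, t)
    if (opts$half_cycle_correction && t == 0) {
      # halve the state-reward share of the first stage
      state_only <- accrue_cycle(occ_vec, NULL, run_params, strategy, t)
      acc <- acc - 0.5 * state_only
    }
    tot <- tot + acc
    if (trace) {
      rows[[t + 1]] <- .trace_row(list(
        cycle = t, age = cohort$start_age + t, occ = occ_vec,
        pe = st$incidences$pe, transplants = st$incidences$transplants,
        cost = acc[["cost"]], qaly = acc[["qaly"]]
      ))
    }
    o <- st$o
    pt <- st$pt
    dead <- st$dead
    occ_end <- .occ_vector(o, pt, dead)
    if (abs(sum(occ_end) - 1) > 1e-9) {
      stop("occupancy mass not conserved at cycle ", t, call. = FALSE)
    }
  }

  final_occ <- .occ_vector(o, pt, dead)
  if (opts$terminal_accrual) {
    acc <- accrue_cycle(final_occ, NULL, run_params, strategy, horizon)
    if (opts$half_cycle_correction) acc <- acc * 0.5
    tot <- tot + acc
    if (trace) {
      rows[[horizon + 1]] <- .trace_row(list(
        cycle = horizon, age = cohort$start_age + horizon, occ = final_occ,
        pe = c(Mild = 0, Moderate = 0, Severe = 0), transplants = 0,
        cost = acc[["cost"]], qaly = acc[["qaly"]]
      ))
    }
  }

  out <- list(
    totals = tot,
    trace = if (trace) do.call(rbind, rows) else NULL,
    final_occupancy = final_occ,
    strategy = strategy,
    spec = cohort
  )
  class(out) <- "cf_trace"
  out
}

.occ_vector <- function(o, pt, dead) {
  out <- c(o, PostTransplant = sum(pt), Dead = dead)
  names(out) <- cf_states()
  attr(out, "pt") <- pt
  out
}

.trace_row <- function(x) {
  if (is.null(x)) {
    return(tibble::tibble(
      cycle = integer(), age = numeric(), Mild = numeric(),
      Moderate = numeric(), Severe = numeric(), PostTransplant = numeric(),
      Dead = numeric(), pe_mild = numeric(), pe_moderate = numeric(),
      pe_severe = numeric(), transplants = numeric(), cost = numeric(),
      qaly = numeric()
    ))
  }
  tibble::tibble(
    cycle = as.integer(x$cycle), age = x$age,
    Mild = x$occ[["Mild"]], Moderate = x$occ[["Moderate"]],
    Severe = x$occ[["Severe"]], PostTransplant = x$occ[["PostTransplant"]],
    Dead = x$occ[["Dead"]],
    pe_mild = x$pe[["Mild"]], pe_moderate = x$pe[["Moderate"]],
    pe_severe = x$pe[["Severe"]],
    transplants = x$transplants, cost = x$cost, qaly = x$qaly
  )
}

#' @export
print.cf_trace <- function(x, ...) {
  cat(sprintf("<cf_trace> %s, %d-year horizon, start age %s\n",
              x$strategy, x$spec$horizon, x$spec$start_age))
  cat(sprintf("  discounted totals: cost $%s, %.3f QALYs\n",
              format(round(x$totals[["cost"]]), big.mark = ","),
              x$totals[["qaly"]]))
  fo <- x$final_occupancy
  cat("  final occupancy:",
      paste(sprintf("%s %.1f%%", names(fo), 100 * fo), collapse = ", "), "\n")
  invisible(x)
}
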