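# Independent brute-force oracle: exhaustive enumeration of every event-tree
# path for a handful of cycles, written as per-patient scalar recursion (no
# occupancy vectors, no shared code with the engine). Used to verify the
# cohort engine on short horizons.
oracle_run <- function(params, strategy, horizon,
                       start = params$cohort$start_distribution) {
  tr <- params$transitions
  co <- params$costs
  ut <- params$utilities
  r <- params$cohort$discount_rate
  treated <- strategy == "treatment"
  e <- params$cohort$efficacy_fraction
  acc <- new.env()
  acc$cost <- 0
  acc$qaly <- 0
  acc$final <- c(Mild = 0, Moderate = 0, Severe = 0, PostTransplant = 0, Dead = 0)

  ptm_at <- function(age_since) {
    sched <- tr$post_transplant_mortality
    idx <- min(1 + age_since, length(sched))
    sched[idx]
  }
  bg_at <- function(age) {
    idx <- min(max(round(age), 0), length(tr$background_mortality) - 1)
    tr$background_mortality[idx + 1] * tr$background_scale
  }

  state_rewards <- function(state, ptage, t, prob) {
    d <- 1 / (1 + r)^t
    if (state == "Dead") return()
    if (state == "PostTransplant") {
      cost <- if (ptage == 1) co$post_transplant_cost_year1 else
        co$post_transplant_cost_later
      acc$cost <- acc$cost + prob * cost * d
      acc$qaly <- acc$qaly + prob * ut$state_utility[["PostTransplant"]] * d
    } else {
      cost <- co$state_cost[[state]]
      if (treated) cost <- cost + co$annual_drug_cost
      acc$cost <- acc$cost + prob * cost * d
      acc$qaly <- acc$qaly + prob * ut$state_utility[[state]] * d
    }
  }

  walk <- function(state, ptage, t, prob) {
    if (prob == 0) return()
    if (t == horizon) {
      if (params$options$terminal_accrual) state_rewards(state, ptage, t, prob)
      acc$final[state] <<- acc$final[state] + prob
      return()
    }
    d <- 1 / (1 + r)^t
    if (state == "Dead") {
      walk("Dead", 0, t + 1, prob)
      return()
    }
    state_rewards(state, ptage, t, prob)
    if (state == "PostTransplant") {
      pdie <- ptm_at(ptage)
      walk("Dead", 0, t + 1, prob * pdie)
      walk("PostTransplant", ptage + 1, t + 1, prob * (1 - pdie))
      return()
    }
    # disease state: exacerbation stratum
    rr_eff <- if (!treated) 1 else if (t == 0) tr$rr_pe_treatment else
      1 - e * (1 - tr$rr_pe_treatment)
    prog_scale <- if (!treated) 1 else if (t == 0) 0 else 1 - e
    improving <- treated && t == 0
    p_pe <- tr$pe[[state]] * rr_eff
    age <- params$cohort$start_age + t
    for (had_pe in c(TRUE, FALSE)) {
      p1 <- prob * if (had_pe) p_pe else 1 - p_pe
      if (p1 == 0) next
      if (had_pe) {
        # exacerbation rewards accrue on every PE path, deaths included
        acc$cost <- acc$cost + p1 * co$pe_cost[[state]] * co$pe_weight * d
        acc$qaly <- acc$qaly + p1 * ut$pe_disutility * d
        pdie <- tr$death_given_pe[[state]]
        walk("Dead", 0, t + 1, p1 * pdie)
        p1 <- p1 * (1 - pdie)
      }
      if (state == "Severe") {
        ptx <- tr$transplant_given_severe
        ptxp <- p1 * ptx
        if (ptxp > 0) {
          acc$cost <- acc$cost + ptxp * co$transplant_cost * d
          walk("Dead", 0, t + 1, ptxp * tr$transplant_year_death)
          walk("PostTransplant", 1, t + 1, ptxp * (1 - tr$transplant_year_death))
        }
        p1 <- p1 * (1 - ptx)
      }
      pmove <- 0
      dest <- state
      if (improving) {
        imp <- if (had_pe) tr$improve_with_pe else tr$improve_no_pe
        if (state == "Moderate") { pmove <- imp[["ModerateToMild"]]; dest <- "Mild" }
        if (state == "Severe") { pmove <- imp[["SevereToModerate"]]; dest <- "Moderate" }
      } else {
        pr <- if (had_pe) tr$progress_with_pe else tr$progress_no_pe
        pr <- pr * prog_scale
        if (state == "Mild") { pmove <- pr[["MildToModerate"]]; dest <- "Moderate" }
        if (state == "Moderate") { pmove <- pr[["ModerateToSevere"]]; dest <- "Severe" }
      }
      q <- bg_at(age)
      for (moved in c(TRUE, FALSE)) {
        p2 <- p1 * if (moved) pmove else 1 - pmove
        if (p2 == 0) next
        s2 <- if (moved) dest else state
        walk("Dead", 0, t + 1, p2 * q)
        walk(s2, 0, t + 1, p2 * (1 - q))
      }
    }
  }

  for (s in names(start)) walk(s, 0, 0, start[[s]])
  list(cost = acc$cost, qaly = acc$qaly, final = acc$final)
}
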