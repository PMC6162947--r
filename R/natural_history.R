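# ---------------------------------------------------------------------------
# Synthetic natural-history stage.
#
# The cohort model's progression probabilities were originally derived by
# bootstrapping an FEV1 cohort forward under literature decline rates, and
# its mortality schedules from registry life tables; neither the FEV1
# distribution, the decline rates nor the life tables are published. This
# module reconstructs those inputs by simulation and calibration against the
# numbers that are published: the pooled progression probabilities, the
# baseline severity split, and the 10-year usual-care cumulative mortality.
# ---------------------------------------------------------------------------

# evaluate expr under a fixed RNG seed without disturbing the caller's stream
.with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic baseline FEV1 cohort
#'
#' Draws `n` FEV1 percent-predicted values from a normal distribution and
#' clips them to the physiological range \[0, 150\]. The defaults (mean 85,
#' sd 14) put about 86% of a 12-year-old cohort above the mild cut-point,
#' approximating the registry severity split at that age.
#'
#' @param n Number of patients (>= 1).
#' @param mean,sd Normal distribution moments (percent predicted); `sd >= 0`.
#' @param age Cohort age in years (metadata).
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return Object of class `cf_fev1_cohort`: list with `values`, `age`,
#'   `seed`, `mean`, `sd`.
#' @export
#' @examples
#' cohort <- generate_fev1_cohort(1000, seed = 1)
#' mean(cohort$values)
generate_fev1_cohort <- function(n, mean = 85, sd = 14, age = 12, seed = 1) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  if (sd < 0) stop("sd must be non-negative", call. = FALSE)
  values <- .with_seed(seed, rnorm(n, mean, sd))
  values <- pmin(pmax(values, 0), 150)
  structure(list(values = values, age = age, seed = seed, mean = mean, sd = sd),
            class = "cf_fev1_cohort")
}

#' Decline-rate pair for the FEV1 bootstrap
#'
#' @param with_pe,without_pe Annual FEV1 decline (percentage points per year)
#'   in years with and without a pulmonary exacerbation;
#'   `with_pe >= without_pe >= 0`.
#' @return Object of class `cf_decline_rates`.
#' @export
decline_rates <- function(with_pe, without_pe) {
  if (!(with_pe >= without_pe && without_pe >= 0)) {
    stop("decline rates must satisfy with_pe >= without_pe >= 0", call. = FALSE)
  }
  structure(list(with_pe = with_pe, without_pe = without_pe),
            class = "cf_decline_rates")
}

#' Progress an FEV1 cohort forward in time
#'
#' For each patient-year, the patient is classified by the 70/40 FEV1
#' cut-points, a pulmonary exacerbation indicator is drawn from the current
#' state's annual PE probability, the matching decline rate is subtracted
#' from FEV1 (floored at 0), and the patient is reclassified.
#'
#' @param cohort A [generate_fev1_cohort()] object.
#' @param rates A [decline_rates()] object.
#' @param pe_prob Named PE probabilities for states `Mild`, `Moderate`,
#'   `Severe` (defaults: registry base-case values).
#' @param years Number of annual steps (>= 1).
#' @param seed Integer seed for the exacerbation draws.
#' @return Object of class `cf_trajectory`: list with `state` (n x years+1
#'   integer matrix, 1 = Mild, 2 = Moderate, 3 = Severe), `pe` (n x years
#'   logical matrix), `fev1` (n x years+1), `ages`, `seed`.
#' @export
progress_cohort <- function(cohort, rates,
                            pe_prob = cf_parameters(calibrate_mortality = FALSE)$transitions$pe,
                            years = 10, seed = 1) {
  stopifnot(inherits(cohort, "cf_fev1_cohort"), inherits(rates, "cf_decline_rates"))
  if (years < 1) stop("years must be >= 1", call. = FALSE)
  if (!all(disease_states() %in% names(pe_prob))) {
    stop("pe_prob must name every reachable state: ",
         paste(setdiff(disease_states(), names(pe_prob)), collapse = ", "),
         call. = FALSE)
  }
  .check_prob(unlist(pe_prob), "pe_prob")
  n <- length(cohort$values)
  state <- matrix(NA_integer_, n, years + 1)
  pe <- matrix(NA, n, years)
  fev1 <- matrix(NA_real_, n, years + 1)
  fev1[, 1] <- cohort$values
  state[, 1] <- as.integer(classify_fev1(fev1[, 1]))
  .with_seed(seed, {
    for (t in seq_len(years)) {
      s <- state[, t]
      p <- unname(pe_prob[disease_states()])[s]
      pe[, t] <- runif(n) < p
      decline <- ifelse(pe[, t], rates$with_pe, rates$without_pe)
      fev1[, t + 1] <- pmax(fev1[, t] - decline, 0)
      state[, t + 1] <- as.integer(classify_fev1(fev1[, t + 1]))
    }
  })
  structure(list(state = state, pe = pe, fev1 = fev1,
                 ages = cohort$age + 0:years, seed = seed),
            class = "cf_trajectory")
}

#' Derive progression probabilities from a bootstrap trajectory
#'
#' For each year and exacerbation stratum, the mild-to-moderate (and
#' moderate-to-severe) progression probability is the fraction of at-risk
#' patients in the better state who are classified in a worse state the next
#' year. Years with an empty at-risk stratum yield `NA`, never 0/0. Pooled
#' values aggregate events and exposure over all years.
#'
#' @param trajectory A [progress_cohort()] trajectory covering >= 2 years.
#' @return List with `per_year` (tibble: `year`, `age`, the four
#'   probabilities) and `pooled` (named vector: `progress_with_pe_mild`,
#'   `progress_no_pe_mild`, `progress_with_pe_moderate`,
#'   `progress_no_pe_moderate`).
#' @export
derive_transition_probabilities <- function(trajectory) {
  stopifnot(inherits(trajectory, "cf_trajectory"))
  years <- ncol(trajectory$pe)
  if (years < 1 || ncol(trajectory$state) < 2) {
    stop("trajectory must cover at least 2 years of states", call. = FALSE)
  }
  keys <- c("progress_with_pe_mild", "progress_no_pe_mild",
            "progress_with_pe_moderate", "progress_no_pe_moderate")
  num <- den <- setNames(numeric(4), keys)
  per <- matrix(NA_real_, years, 4, dimnames = list(NULL, keys))
  for (t in seq_len(years)) {
    s <- trajectory$state[, t]
    s2 <- trajectory$state[, t + 1]
    p <- trajectory$pe[, t]
    sel <- list(
      progress_with_pe_mild = s == 1 & p,
      progress_no_pe_mild = s == 1 & !p,
      progress_with_pe_moderate = s == 2 & p,
      progress_no_pe_moderate = s == 2 & !p
    )
    worse <- list(s2 > 1, s2 > 1, s2 > 2, s2 > 2)
    for (k in seq_along(keys)) {
      at_risk <- sum(sel[[k]])
      if (at_risk > 0) {
        ev <- sum(worse[[k]] & sel[[k]])
        per[t, k] <- ev / at_risk
        num[k] <- num[k] + ev
        den[k] <- den[k] + at_risk
      }
    }
  }
  pooled <- ifelse(den > 0, num / den, NA_real_)
  per_year <- tibble::as_tibble(as.data.frame(per))
  per_year <- tibble::add_column(per_year,
                                 year = seq_len(years),
                                 age = trajectory$ages[seq_len(years)],
                                 .before = 1)
  list(per_year = per_year, pooled = pooled)
}

#' Calibrate FEV1 decline rates against target progression probabilities
#'
#' Searches for the decline-rate pair whose bootstrap-derived pooled
#' progression probabilities best match the four target probabilities
#' (mild-to-moderate and moderate-to-severe, each with and without
#' exacerbation), by least squares. Because the simulated objective is
#' piecewise constant in the rates (patients cross thresholds discretely),
#' the search is a deterministic two-stage grid under common random numbers
#' rather than a gradient or simplex method.
#'
#' @param targets Named numeric vector of the four pooled targets (names as
#'   in [derive_transition_probabilities()] `pooled`); defaults to the
#'   registry base-case values.
#' @param search_bounds List with `with_pe` and `without_pe` ranges.
#' @param n Bootstrap cohort size.
#' @param seed Integer seed (shared by every objective evaluation).
#' @param mean,sd,age Baseline cohort settings, see [generate_fev1_cohort()].
#' @param pe_prob Per-state PE probabilities used in the bootstrap.
#' @param years Bootstrap length in years.
#' @param tolerance Acceptable root-mean-square residual per probability.
#' @return Object of class `cf_decline_fit`: list with `rates`
#'   ([decline_rates()]), `residual_rms`, `derived` (pooled probabilities at
#'   the optimum), `targets`, `converged` (residual <= tolerance), `n`,
#'   `seed`.
#' @export
calibrate_decline_rates <- function(targets = c(progress_with_pe_mild = 0.0697,
                                                progress_no_pe_mild = 0.0307,
                                                progress_with_pe_moderate = 0.0617,
                                                progress_no_pe_moderate = 0.0279),
                                    search_bounds = list(with_pe = c(0, 8),
                                                         without_pe = c(0, 5)),
                                    n = 1000, seed = 1,
                                    mean = 85, sd = 14, age = 12,
                                    pe_prob = c(Mild = 0.3213, Moderate = 0.5748,
                                                Severe = 0.6794),
                                    years = 10, tolerance = 0.05) {
  if (any(targets < 0) || any(targets >= 1)) {
    stop("targets must lie in [0, 1)", call. = FALSE)
  }
  cohort <- generate_fev1_cohort(n, mean, sd, age, seed)
  pooled_at <- function(d_pe, d_no) {
    traj <- progress_cohort(cohort, decline_rates(d_pe, d_no), pe_prob,
                            years = years, seed = seed)
    derive_transition_probabilities(traj)$pooled
  }
  obj <- function(d_pe, d_no) {
    p <- pooled_at(d_pe, d_no)
    p[is.na(p)] <- 0
    sum((p[names(targets)] - targets)^2)
  }
  if (all(targets == 0)) {
    # no progression: the zero-decline pair reproduces it exactly
    rates <- decline_rates(0, 0)
    return(structure(list(rates = rates, residual_rms = 0,
                          derived = setNames(rep(0, 4), names(targets)),
                          targets = targets, converged = TRUE,
                          n = n, seed = seed), class = "cf_decline_fit"))
  }
  grid_search <- function(b_pe, b_no, len) {
    g <- expand.grid(d_pe = seq(b_pe[1], b_pe[2], length.out = len),
                     d_no = seq(b_no[1], b_no[2], length.out = len))
    g <- g[g$d_pe >= g$d_no, , drop = FALSE]
    v <- mapply(obj, g$d_pe, g$d_no)
    g[which.min(v), ]
  }
  b1 <- grid_search(search_bounds$with_pe, search_bounds$without_pe, 15)
  span_pe <- diff(search_bounds$with_pe) / 14
  span_no <- diff(search_bounds$without_pe) / 14
  b2 <- grid_search(
    pmax(c(b1$d_pe - span_pe, b1$d_pe + span_pe), 0),
    pmax(c(b1$d_no - span_no, b1$d_no + span_no), 0), 13
  )
  if (b2$d_pe > max(search_bounds$with_pe) + 1e-9 ||
      b2$d_no > max(search_bounds$without_pe) + 1e-9) {
    stop("optimizer left the search bounds; best residual ",
         signif(sqrt(obj(b2$d_pe, b2$d_no) / 4), 4), call. = FALSE)
  }
  derived <- pooled_at(b2$d_pe, b2$d_no)
  residual_rms <- sqrt(obj(b2$d_pe, b2$d_no) / length(targets))
  structure(list(
    rates = decline_rates(b2$d_pe, max(b2$d_no, 0)),
    residual_rms = residual_rms,
    derived = derived,
    targets = targets,
    converged = residual_rms <= tolerance,
    n = n, seed = seed
  ), class = "cf_decline_fit")
}

#' Convert a trial-period event probability to a 1-year probability
#'
#' Assumes a constant event hazard within the period:
#' `p_year = 1 - (1 - p_period)^(52 / period_weeks)`. A period probability
#' of 1 saturates at 1 for any finite period.
#'
#' @param p_period Event probability over the observation period, in \[0, 1\].
#' @param period_weeks Observation period length in weeks (> 0).
#' @return 1-year event probability.
#' @export
#' @examples
#' annualize_event_probability(0.3, 24)
annualize_event_probability <- function(p_period, period_weeks) {
  if (any(p_period < 0) || any(p_period > 1)) {
    stop("p_period must lie in [0, 1]", call. = FALSE)
  }
  if (any(period_weeks <= 0)) stop("period_weeks must be > 0", call. = FALSE)
  1 - (1 - p_period)^(52 / period_weeks)
}

#' Convert a trial-period event rate to a 1-year probability
#'
#' Alternative input pathway for rate-per-patient trial summaries:
#' `p_year = 1 - exp(-rate * 52 / period_weeks)` under a constant hazard.
#'
#' @param rate_per_period Events per patient over the period (>= 0).
#' @param period_weeks Observation period length in weeks (> 0).
#' @return 1-year probability of at least one event.
#' @export
annualize_event_rate <- function(rate_per_period, period_weeks) {
  if (any(rate_per_period < 0)) stop("rate must be non-negative", call. = FALSE)
  if (any(period_weeks <= 0)) stop("period_weeks must be > 0", call. = FALSE)
  1 - exp(-rate_per_period * 52 / period_weeks)
}

#' 1-year relative risk of pulmonary exacerbation
#'
#' @param p_treatment_year,p_usualcare_year 1-year exacerbation
#'   probabilities; the usual-care probability must be positive.
#' @return Unitless relative risk (treatment vs usual care).
#' @export
relative_risk <- function(p_treatment_year, p_usualcare_year) {
  if (any(p_usualcare_year <= 0)) {
    stop("usual-care probability must be > 0", call. = FALSE)
  }
  p_treatment_year / p_usualcare_year
}

#' Calibrate the flat background CF mortality hazard
#'
#' Solves for the flat annual background hazard at which the usual-care
#' cohort (age 12, registry severity split) reaches the target cumulative
#' mortality over the stated horizon when run through the full cycle event
#' tree (so exacerbation, transplant and post-transplant deaths are all
#' accounted for).
#'
#' @param params A `cf_parameters` object (its background schedule is
#'   ignored during the search).
#' @param target_cumulative Target cumulative death fraction in (0, 1);
#'   default 0.151, the published 10-year usual-care value.
#' @param horizon Horizon in years over which the target applies.
#' @param bounds Hazard search interval.
#' @return The calibrated annual hazard (scalar).
#' @export
calibrate_background_hazard <- function(params, target_cumulative = 0.151,
                                        horizon = 10, bounds = c(0, 0.2)) {
  if (target_cumulative <= 0 || target_cumulative >= 1) {
    stop("target_cumulative must lie in (0, 1)", call. = FALSE)
  }
  anchor <- .mortality_anchor()
  spec <- list(start_age = anchor$start_age,
               start_distribution = anchor$start_distribution,
               horizon = horizon)
  f <- function(h) {
    p <- params
    p$transitions$background_mortality <- rep(h, 111)
    p$transitions$background_scale <- 1
    run_cohort(p, "usual_care", spec = spec, trace = FALSE)$final_occupancy[["Dead"]] -
      target_cumulative
  }
  f_lo <- f(bounds[1])
  if (f_lo > 0) {
    stop("target cumulative mortality ", target_cumulative,
         " is below the mortality induced by the event tree alone (",
         signif(f_lo + target_cumulative, 4), "); unreachable within bounds",
         call. = FALSE)
  }
  if (f(bounds[2]) < 0) {
    stop("target cumulative mortality unreachable within hazard bounds ",
         "[", bounds[1], ", ", bounds[2], "]", call. = FALSE)
  }
  uniroot(f, bounds, tol = 1e-10)$root
}

#' Build a mortality schedule
#'
#' `"background_cf"` returns a flat age-indexed annual hazard calibrated with
#' [calibrate_background_hazard()] (a zero target yields the all-zero
#' schedule); the schedule object accepts arbitrary age-indexed values for
#' users who transcribe a published life table. `"post_transplant"` returns a
#' years-since-transplant schedule whose first element is the transplant-year
#' death probability and whose tail is a declining sequence (last value
#' recycled beyond the stated years).
#'
#' @param kind `"background_cf"` or `"post_transplant"`.
#' @param params Parameters used for background calibration.
#' @param target_cumulative Cumulative usual-care mortality target
#'   (background kind).
#' @param years Horizon for the cumulative target.
#' @param ages Age grid for the background schedule.
#' @param first_year Transplant-year death probability
#'   (post-transplant kind).
#' @param tail Declining later-year probabilities (post-transplant kind).
#' @return Object of class `cf_mortality_schedule`: list with `kind`,
#'   `index`, `prob` and calibration metadata.
#' @export
build_mortality_schedule <- function(kind = c("background_cf", "post_transplant"),
                                     params = NULL,
                                     target_cumulative = 0.151, years = 10,
                                     ages = 0:110,
                                     first_year = 0.297,
                                     tail = c(0.10, 0.09, 0.08, 0.08, 0.07)) {
  kind <- match.arg(kind)
  if (kind == "background_cf") {
    if (target_cumulative == 0) {
      return(structure(list(kind = kind, index = ages,
                            prob = rep(0, length(ages)),
                            target_cumulative = 0, years = years),
                       class = "cf_mortality_schedule"))
    }
    if (is.null(params)) params <- cf_parameters(calibrate_mortality = FALSE)
    h <- calibrate_background_hazard(params, target_cumulative, years)
    structure(list(kind = kind, index = ages, prob = rep(h, length(ages)),
                   hazard = h, target_cumulative = target_cumulative,
                   years = years),
              class = "cf_mortality_schedule")
  } else {
    .check_prob(first_year, "first_year")
    .check_prob(tail, "tail")
    prob <- c(first_year, tail)
    structure(list(kind = kind, index = seq_along(prob), prob = prob),
              class = "cf_mortality_schedule")
  }
}

#' @export
print.cf_decline_fit <- function(x, ...) {
  cat(sprintf("<cf_decline_fit> decline %.2f (PE years) / %.2f (non-PE) %%-points per year\n",
              x$rates$with_pe, x$rates$without_pe))
  cat(sprintf("  residual RMS %.4f over %d targets (n = %d, seed = %d)%s\n",
              x$residual_rms, length(x$targets), x$n, x$seed,
              if (x$converged) "" else "  [above tolerance]"))
  invisible(x)
}
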