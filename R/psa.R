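# ---------------------------------------------------------------------------
# Probabilistic sensitivity analysis: second-order parameter uncertainty and
# the cost-effectiveness acceptability curve.
# ---------------------------------------------------------------------------

#' Assign probability distributions to the registered parameters
#'
#' Builds the second-order uncertainty distributions used by [sample_psa()]:
#' beta for probabilities and utilities, gamma for costs, and lognormal for
#' the exacerbation relative risk, as is conventional for each quantity's
#' support. One-way ranges are interpreted as 95% intervals, so the standard
#' error is `(high - low) / (2 * 1.96)`; distribution parameters are
#' moment-matched so each distribution's mean equals the base-case value
#' (the lognormal uses `meanlog = log(base) - sdlog^2 / 2`). The
#' exacerbation disutility is drawn as a beta-distributed magnitude and
#' negated. Parameters whose family is `none` (calibrated schedules) are
#' held fixed. A zero-width range yields a degenerate (fixed) draw.
#'
#' @param params A [cf_parameters()] object.
#' @param ranges Range table as returned by [oneway_ranges()].
#' @return Object of class `cf_psa_distributions`: named list of per-
#'   parameter specifications (`family` plus family-specific parameters).
#' @export
psa_distributions <- function(params, ranges = oneway_ranges(params)) {
  dists <- list()
  for (i in seq_len(nrow(ranges))) {
    id <- ranges$id[i]
    family <- ranges$family[i]
    base <- ranges$base[i]
    se <- (ranges$high[i] - ranges$low[i]) / (2 * 1.96)
    if (family == "none") next
    if (se < 1e-12) {
      dists[[id]] <- list(family = "fixed", value = base)
      next
    }
    d <- switch(family,
      beta = {
        m <- base
        v <- se^2
        if (m <= 0 || m >= 1) {
          stop("beta moment matching failed for '", id,
               "': mean must lie in (0, 1)", call. = FALSE)
        }
        if (v >= m * (1 - m)) {
          stop("beta moment matching failed for '", id,
               "': variance too large for the (0, 1) support", call. = FALSE)
        }
        k <- m * (1 - m) / v - 1
        list(family = "beta", shape1 = m * k, shape2 = (1 - m) * k)
      },
      beta_neg = {
        m <- -base
        v <- se^2
        if (v >= m * (1 - m)) {
          stop("beta moment matching failed for '", id, "'", call. = FALSE)
        }
        k <- m * (1 - m) / v - 1
        list(family = "beta_neg", shape1 = m * k, shape2 = (1 - m) * k)
      },
      gamma = {
        list(family = "gamma", shape = base^2 / se^2, rate = base / se^2)
      },
      lognormal = {
        sdlog <- (log(ranges$high[i]) - log(ranges$low[i])) / (2 * 1.96)
        list(family = "lognormal", meanlog = log(base) - sdlog^2 / 2,
             sdlog = sdlog)
      },
      stop("unknown distribution family '", family, "'", call. = FALSE)
    )
    dists[[id]] <- d
  }
  structure(dists, class = "cf_psa_distributions")
}

#' Expected value of a PSA distribution
#'
#' @param d One element of [psa_distributions()].
#' @return The distribution mean (matches the base-case value by
#'   construction).
#' @export
psa_distribution_mean <- function(d) {
  switch(d$family,
    fixed = d$value,
    beta = d$shape1 / (d$shape1 + d$shape2),
    beta_neg = -d$shape1 / (d$shape1 + d$shape2),
    gamma = d$shape / d$rate,
    lognormal = exp(d$meanlog + d$sdlog^2 / 2),
    stop("unknown family")
  )
}

.psa_draw <- function(d, n) {
  switch(d$family,
    fixed = rep(d$value, n),
    beta = rbeta(n, d$shape1, d$shape2),
    beta_neg = -rbeta(n, d$shape1, d$shape2),
    gamma = rgamma(n, shape = d$shape, rate = d$rate),
    lognormal = rlnorm(n, d$meanlog, d$sdlog),
    stop("unknown family")
  )
}

#' Second-order Monte Carlo (probabilistic sensitivity) analysis
#'
#' Draws `n` independent parameter sets from the assigned distributions
#' (parameters are sampled independently; calibrated schedules and the
#' starting distribution are held fixed) and runs both strategy arms for
#' each draw at the base cohort spec.
#'
#' @param params A [cf_parameters()] object.
#' @param dists Distributions from [psa_distributions()].
#' @param n Number of draws (>= 1); the published analysis uses 10,000.
#' @param seed Integer seed; identical seeds give identical samples.
#' @param spec Optional cohort overrides as in [run_cohort()].
#' @return Object of class `cf_psa`: a tibble with one row per draw
#'   (`draw`, `cost_uc`, `qaly_uc`, `cost_tx`, `qaly_tx`, `dcost`, `dqaly`)
#'   with the draw matrix in attribute `draws` and the seed in attribute
#'   `seed`.
#' @export
sample_psa <- function(params, dists = psa_distributions(params), n = 10000,
                       seed = 1, spec = NULL) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  ids <- names(dists)
  draws <- .with_seed(seed, {
    m <- vapply(dists, .psa_draw, numeric(n), n = n)
    if (n == 1) m <- matrix(m, nrow = 1, dimnames = list(NULL, ids))
    m
  })
  cost_uc <- qaly_uc <- cost_tx <- qaly_tx <- numeric(n)
  for (i in seq_len(n)) {
    p <- params
    for (id in ids) p <- param_set(p, id, draws[i, id], validate = FALSE)
    uc <- run_cohort(p, "usual_care", spec = spec, trace = FALSE)
    tx <- run_cohort(p, "treatment", spec = spec, trace = FALSE)
    cost_uc[i] <- uc$totals[["cost"]]; qaly_uc[i] <- uc$totals[["qaly"]]
    cost_tx[i] <- tx$totals[["cost"]]; qaly_tx[i] <- tx$totals[["qaly"]]
  }
  out <- tibble::tibble(
    draw = seq_len(n),
    cost_uc = cost_uc, qaly_uc = qaly_uc,
    cost_tx = cost_tx, qaly_tx = qaly_tx,
    dcost = cost_tx - cost_uc, dqaly = qaly_tx - qaly_uc
  )
  attr(out, "draws") <- draws
  attr(out, "seed") <- seed
  class(out) <- c("cf_psa", class(out))
  out
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the probability that treatment is
#' cost-effective is the fraction of PSA draws with non-negative incremental
#' net monetary benefit, `wtp * dqaly - dcost >= 0`.
#'
#' @param samples A [sample_psa()] result (or any data frame with `dcost`
#'   and `dqaly` columns).
#' @param wtp_grid Non-empty numeric vector of willingness-to-pay values
#'   (USD per QALY).
#' @return Object of class `cf_ceac`: tibble with columns `wtp` and
#'   `prob_cost_effective`.
#' @export
ceac <- function(samples, wtp_grid = seq(0, 6e6, by = 1e5)) {
  if (!all(c("dcost", "dqaly") %in% names(samples))) {
    stop("samples must have dcost and dqaly columns", call. = FALSE)
  }
  if (nrow(samples) == 0) stop("samples must be non-empty", call. = FALSE)
  if (length(wtp_grid) == 0) stop("wtp_grid must be non-empty", call. = FALSE)
  prob <- vapply(wtp_grid, function(l) {
    mean(l * samples$dqaly - samples$dcost >= 0)
  }, 0)
  out <- tibble::tibble(wtp = wtp_grid, prob_cost_effective = prob)
  class(out) <- c("cf_ceac", class(out))
  out
}

#' Plot a cost-effectiveness acceptability curve
#'
#' @param curve A [ceac()] result.
#' @return A ggplot object.
#' @export
plot_ceac <- function(curve) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$wtp,
                                      y = .data$prob_cost_effective)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (USD per QALY)",
                  y = "Probability cost-effective") +
    ggplot2::theme_minimal()
}

#' Plot a tornado diagram
#'
#' @param tornado_tbl A [tornado()] result.
#' @return A ggplot object.
#' @export
plot_tornado <- function(tornado_tbl) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  tb <- tornado_tbl
  tb$id <- factor(tb$id, levels = rev(tb$id))
  ggplot2::ggplot(tb, ggplot2::aes(y = .data$id)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$icer_low,
                                       xend = .data$icer_high,
                                       yend = .data$id), linewidth = 3) +
    ggplot2::geom_vline(xintercept = attr(tornado_tbl, "icer_base"),
                        linetype = 2) +
    ggplot2::labs(x = "ICER (USD per QALY)", y = NULL) +
    ggplot2::theme_minimal()
}
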