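# ---------------------------------------------------------------------------
# Report generation: the full default analysis grid, compared side by side
# with the published reference results.
# ---------------------------------------------------------------------------

#' Published reference results for validation
#'
#' Reported results of the published cost-effectiveness analysis that this
#' model re-implements, used by [reproduce_results()] to tabulate absolute
#' and relative deviations. Costs in 2016 USD, QALYs per patient, ICERs in
#' USD per QALY; values as printed (whole dollars, 2-decimal QALYs).
#'
#' @return A tibble with columns `label`, `metric`, `reference`.
#' @export
reference_results <- function() {
  tab3 <- function(label, cost_uc, qaly_uc, cost_tx, qaly_tx, icer) {
    tibble::tibble(
      label = label,
      metric = c("cost_uc", "qaly_uc", "cost_tx", "qaly_tx", "icer"),
      reference = c(cost_uc, qaly_uc, cost_tx, qaly_tx, icer)
    )
  }
  icer_only <- function(label, icer) {
    tibble::tibble(label = label, metric = "icer", reference = icer)
  }
  rbind(
    tab3("base_2", 30469, 2.23, 562075, 2.30, 7311801),
    tab3("worst_2", 30469, 2.23, 562731, 2.28, 9292285),
    tab3("base_4", 51850, 3.56, 904313, 3.70, 5835535),
    tab3("worst_4", 51850, 3.56, 907652, 3.65, 9554343),
    tab3("base_6", 72361, 4.77, 1221224, 5.00, 4869328),
    tab3("worst_6", 72361, 4.77, 1228079, 4.89, 9263760),
    tab3("base_8", 94274, 5.86, 1512761, 6.20, 4173169),
    tab3("worst_8", 94274, 5.86, 1523930, 6.02, 8861944),
    tab3("base_10", 116156, 6.84, 1778921, 7.29, 3655352),
    tab3("worst_10", 116156, 6.84, 1794056, 7.04, 8480265),
    icer_only("efficacy_75", 4168163),
    icer_only("efficacy_50", 4930230),
    icer_only("efficacy_25", 6165464),
    icer_only("age_6", 5088950),
    icer_only("age_25", 1321306),
    icer_only("high_cost", 3480135),
    tibble::tibble(label = "threshold", metric = "threshold_cost",
                   reference = 4153)
  )
}

.write_csv_with_header <- function(df, path, meta) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta)) {
    writeLines(sprintf("# %s: %s", nm, meta[[nm]]), con)
  }
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

.params_hash <- function(params) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_parameters(params, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full default analysis and write a report bundle
#'
#' Runs the packaged scenario grid (restricted to `horizons`), the threshold
#' price search, the one-way tornado analysis and (optionally) the
#' probabilistic sensitivity analysis, writing each result as a CSV with a
#' commented metadata header, plus a side-by-side comparison of every
#' computed quantity against the published reference value with absolute and
#' relative deviations, and a run manifest listing all outputs.
#'
#' @param output_dir Directory for the bundle (created if needed).
#' @param params A [cf_parameters()] object.
#' @param horizons Horizons (years) to keep from the default grid.
#' @param n_psa PSA draws (0 skips the PSA stage).
#' @param seed Integer seed for the PSA stage.
#' @return Invisibly, a list with the computed tables (`scenarios`,
#'   `comparison`, `threshold`, `tornado`, `psa_summary`, `ceac`) and the
#'   manifest.
#' @export
reproduce_results <- function(output_dir, params = cf_parameters(),
                              horizons = c(2, 4, 6, 8, 10),
                              n_psa = 10000, seed = 1) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  version <- as.character(utils::packageVersion("cfcea"))
  hash <- .params_hash(params)
  meta <- list(package = paste("cfcea", version), parameter_hash = hash,
               seed = seed, created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  outputs <- character()
  add_output <- function(df, name, extra = list()) {
    path <- file.path(output_dir, name)
    .write_csv_with_header(df, path, c(meta, extra))
    outputs <<- c(outputs, path)
    path
  }

  grid <- default_scenario_grid()
  grid <- grid[grid$horizon %in% horizons, ]
  scenarios <- run_scenarios(params, grid)
  add_output(scenarios, "scenarios.csv")

  thr <- NULL
  if (10 %in% horizons) {
    thr <- threshold_drug_cost(params)
    add_output(tibble::tibble(wtp = params$cohort$wtp,
                              threshold_cost = thr$threshold_cost,
                              icer_at_threshold = thr$icer_at_threshold),
               "threshold.csv")
  }

  torn <- tornado(params)
  add_output(torn, "tornado.csv")

  psa_summary <- ceac_tbl <- NULL
  if (n_psa > 0) {
    psa <- sample_psa(params, n = n_psa, seed = seed)
    psa_summary <- tibble::tibble(
      n = n_psa, seed = seed,
      mean_dcost = mean(psa$dcost), mean_dqaly = mean(psa$dqaly),
      sd_dcost = stats::sd(psa$dcost), sd_dqaly = stats::sd(psa$dqaly)
    )
    add_output(psa_summary, "psa_summary.csv")
    ceac_tbl <- ceac(psa)
    add_output(as.data.frame(ceac_tbl), "ceac.csv")
  }

  computed <- rbind(
    tibble::tibble(
      label = rep(scenarios$label, each = 5),
      metric = rep(c("cost_uc", "qaly_uc", "cost_tx", "qaly_tx", "icer"),
                   nrow(scenarios)),
      computed = as.numeric(t(as.matrix(
        scenarios[, c("cost_uc", "qaly_uc", "cost_tx", "qaly_tx", "icer")]
      )))
    ),
    if (!is.null(thr)) {
      tibble::tibble(label = "threshold", metric = "threshold_cost",
                     computed = thr$threshold_cost)
    }
  )
  comparison <- merge(reference_results(), computed,
                      by = c("label", "metric"), sort = FALSE)
  comparison <- tibble::as_tibble(comparison)
  comparison$abs_deviation <- comparison$computed - comparison$reference
  comparison$rel_deviation <- comparison$abs_deviation / comparison$reference
  add_output(comparison, "comparison.csv")

  manifest <- tibble::tibble(
    command = "reproduce_results",
    package_version = version,
    parameter_hash = hash,
    seed = seed,
    output = basename(outputs)
  )
  .write_csv_with_header(manifest, file.path(output_dir, "manifest.csv"), meta)

  invisible(list(scenarios = scenarios, comparison = comparison,
                 threshold = thr, tornado = torn, psa_summary = psa_summary,
                 ceac = ceac_tbl, manifest = manifest))
}
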