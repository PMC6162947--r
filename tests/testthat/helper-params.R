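# Shared fixtures: build the calibrated default parameter set once per run.
default_params <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- cf_parameters()
    cache
  }
})

# parameters with no background mortality (no calibration run)
plain_params <- function(overrides = list()) {
  cf_parameters(overrides, calibrate_mortality = FALSE)
}

# a configuration in which nothing happens except what the caller turns on:
# no deaths, no exacerbations, no transplant, no progression, no discounting
inert_params <- function(overrides = list()) {
  base <- list(
    transitions = list(
      pe = c(Mild = 0, Moderate = 0, Severe = 0),
      death_given_pe = c(Mild = 0, Moderate = 0, Severe = 0),
      progress_with_pe = c(MildToModerate = 0, ModerateToSevere = 0),
      progress_no_pe = c(MildToModerate = 0, ModerateToSevere = 0),
      transplant_given_severe = 0,
      transplant_year_death = 0,
      improve_with_pe = c(ModerateToMild = 0, SevereToModerate = 0),
      improve_no_pe = c(ModerateToMild = 0, SevereToModerate = 0),
      post_transplant_mortality = c(0, 0)
    ),
    cohort = list(discount_rate = 0)
  )
  merged <- utils::modifyList(base, overrides)
  cf_parameters(merged, calibrate_mortality = FALSE)
}
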