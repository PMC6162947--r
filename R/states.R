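#' Health states of the cystic fibrosis cohort model
#'
#' The model follows a cohort through five mutually exclusive health states:
#' three FEV1-defined disease-severity states, a post-lung-transplant state,
#' and death. Severity cut-points on FEV1 percent predicted are strict:
#' mild is FEV1 > 70, severe is FEV1 < 40, moderate is the closed band in
#' between. Death is absorbing; repeat transplantation is not modelled, so
#' post-transplant occupants can only remain post-transplant or die.
#'
#' @return Character vector of the five state labels, in model order.
#' @export
#' @examples
#' cf_states()
cf_states <- function() {
  c("Mild", "Moderate", "Severe", "PostTransplant", "Dead")
}

# disease (live, non-transplant) states that face the exacerbation event tree
disease_states <- function() c("Mild", "Moderate", "Severe")

#' Is a state absorbing?
#'
#' @param state Character vector of state labels.
#' @return Logical vector; `TRUE` only for `"Dead"`.
#' @export
is_absorbing_state <- function(state) {
  stopifnot(all(state %in% cf_states()))
  state == "Dead"
}

#' Classify FEV1 percent predicted into severity states
#'
#' Applies the strict cut-points used throughout the model: mild for
#' FEV1 > 70, severe for FEV1 < 40, moderate otherwise.
#'
#' @param fev1 Numeric vector of FEV1 percent-predicted values.
#' @return Factor with levels `Mild`, `Moderate`, `Severe`.
#' @export
#' @examples
#' classify_fev1(c(85, 70, 55, 40, 39.9))
classify_fev1 <- function(fev1) {
  stopifnot(is.numeric(fev1), all(is.finite(fev1)))
  out <- ifelse(fev1 > 70, "Mild", ifelse(fev1 < 40, "Severe", "Moderate"))
  factor(out, levels = disease_states())
}

#' Registry-based starting severity distribution by age
#'
#' Prevalence of mild/moderate/severe disease among persons with CF at the
#' supported cohort starting ages, as reported in the national patient
#' registry: age 6 is 95/4/1, age 12 is 87/11/2, age 25 is 46/37/17
#' (percent mild/moderate/severe).
#'
#' @param age Starting age in years; one of 6, 12 or 25.
#' @return Named numeric vector over `Mild`, `Moderate`, `Severe`, summing to 1.
#' @export
#' @examples
#' age_start_distribution(12)
age_start_distribution <- function(age) {
  dist <- switch(as.character(age),
    "6"  = c(Mild = 0.95, Moderate = 0.04, Severe = 0.01),
    "12" = c(Mild = 0.87, Moderate = 0.11, Severe = 0.02),
    "25" = c(Mild = 0.46, Moderate = 0.37, Severe = 0.17),
    stop("no registry starting distribution for age ", age,
         "; supported ages are 6, 12 and 25", call. = FALSE)
  )
  dist
}
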