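# Base-case model inputs for the cystic fibrosis cost-effectiveness model.
# All probabilities are per 1-year cycle; costs are 2016 USD.
# Any key may be omitted (packaged defaults apply); unknown keys are rejected.
transitions:
  # annual probability of at least one pulmonary exacerbation, by severity state
  pe:
    Mild: 0.3213
    Moderate: 0.5748
    Severe: 0.6794
  # probability of death given an exacerbation
  death_given_pe:
    Mild: 0.001
    Moderate: 0.001
    Severe: 0.2174
  # disease progression conditional on exacerbation status
  progress_with_pe:
    MildToModerate: 0.0697
    ModerateToSevere: 0.0617
  progress_no_pe:
    MildToModerate: 0.0307
    ModerateToSevere: 0.0279
  # transplant uptake among severe survivors (same with and without exacerbation)
  transplant_given_severe: 0.078
  # death in the transplant year
  transplant_year_death: 0.297
  # treatment-arm improvement transitions (first treatment year only)
  improve_with_pe:
    ModerateToMild: 0.1045
    SevereToModerate: 0.5455
  improve_no_pe:
    ModerateToMild: 0.0935
    SevereToModerate: 0.5517
  # relative risk of pulmonary exacerbation on treatment vs usual care
  rr_pe_treatment: 0.74
  # multiplier on the background mortality schedule (sensitivity handle)
  background_scale: 1
  # annual death probability by years since transplant; element 1 is the
  # transplant year, later elements a declining tail (last value recycled);
  # the tail is a synthetic reconstruction shaped like published post-
  # transplant survival in CF
  post_transplant_mortality: [0.297, 0.10, 0.09, 0.08, 0.08, 0.07]
  # background_mortality: omitted -> calibrated flat hazard (10-year
  # usual-care cumulative mortality of 15.1%)
costs:
  # net payer price, 72% of the average wholesale price
  annual_drug_cost: 188660.43
  # annual maintenance cost of each severity state
  state_cost:
    Mild: 7566.91
    Moderate: 9981.89
    Severe: 17226.80
  # cost per exacerbation cycle
  pe_cost:
    Mild: 2575.97
    Moderate: 8371.90
    Severe: 52646.40
  # one-time double-lung-transplant cost, charged in the transplant cycle
  transplant_cost: 1056002.23
  post_transplant_cost_year1: 87945.85
  post_transplant_cost_later: 86332.56
  awp_fraction: 0.72
  # multiplicative weight on exacerbation costs (more than one event per cycle)
  pe_weight: 1
utilities:
  state_utility:
    Mild: 0.86
    Moderate: 0.81
    Severe: 0.64
    PostTransplant: 0.83
  pe_disutility: -0.17
  dead_utility: 0
cohort:
  start_age: 12
  # registry severity split at age 12
  start_distribution:
    Mild: 0.87
    Moderate: 0.11
    Severe: 0.02
  horizon: 10
  cycle_length: 1
  discount_rate: 0.03
  efficacy_fraction: 1
  wtp: 150000
options:
  terminal_accrual: true
  half_cycle_correction: false
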