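# cfcea

Cost-effectiveness modelling of lumacaftor/ivacaftor combination therapy for
cystic fibrosis (CF) patients homozygous for the F508del CFTR mutation, from
a United States payer perspective.

CFTR modulators produce real clinical benefit — fewer pulmonary
exacerbations, preserved lung function — at list prices near $190,000 per
patient-year net of rebates. Whether that trade is acceptable is a question
for decision modelling: this package implements the Markov cohort
state-transition model used to answer it, as tested, configurable R code.
It is aimed at health-economics and outcomes researchers who want to
re-run, perturb or extend the analysis rather than read a single set of
published numbers.

## The model

A cohort of CF patients (default: 12-year-olds, 87/11/2% mild/moderate/
severe) moves annually among five states defined by FEV1 percent predicted —
mild (> 70), moderate (40–70), severe (< 40) — plus post-lung-transplant and
dead. Pulmonary exacerbation (PE) and lung transplant are within-cycle
transition events. Each strategy arm *s* accrues discounted costs and QALYs

```
C_s = Σ_t  c_s(t) / (1 + r)^t        E_s = Σ_t  u_s(t) / (1 + r)^t
```

with r = 3%, and the primary outcome is the incremental cost-effectiveness
ratio

```
ICER = (C_tx − C_uc) / (E_tx − E_uc)   [USD per QALY gained]
```

judged against a willingness-to-pay of $150,000/QALY. Treatment multiplies
the PE probability by a relative risk of 0.74, suspends progression, and
allows first-year improvement transitions; long-term effectiveness scenarios
blend these effects linearly from the second year onward. Unpublished
nuisance inputs (background CF mortality, post-transplant mortality, FEV1
decline rates) are reconstructed by calibration against published anchors —
see the methods vignette (`vignettes/model-methods.Rmd`).

## Worked example

```r
library(cfcea)

params <- cf_parameters()        # registry defaults + mortality calibration
uc <- run_cohort(params, "usual_care")
tx <- run_cohort(params, "treatment")
compute_icer(tx, uc)
#> <cf_icer>
#>   usual care: $120,977, 6.927 QALYs
#>   treatment : $1,788,919, 7.348 QALYs
#>   incremental: $1,667,942 / 0.420 QALYs -> ICER $3,970,962 per QALY
```

Over ten years, usual care costs about $121k and yields 6.93 QALYs per
patient; adding lumacaftor/ivacaftor costs $1.79M and yields 7.35 QALYs.
Each QALY gained therefore costs roughly $4.0M — more than twenty-five
times the willingness-to-pay benchmark. The price at which the treatment
*would* be cost-effective:

```r
threshold_drug_cost(params, wtp = 150000)$threshold_cost
#> [1] 10955.57
```

i.e. about $11k/year versus the actual ~$189k/year. Scenario, one-way and
probabilistic sensitivity analyses:

```r
run_scenarios(params)                    # horizons, efficacy, ages, high cost
tornado(params, top_k = 15)              # one-way ICER ranges, ranked
psa <- sample_psa(params, n = 10000, seed = 1)
ceac(psa)                                # acceptability curve
reproduce_results("report")              # full bundle + reference comparison
```

A thin command-line wrapper with the same capabilities ships at
`inst/cli/cfcea.R` (`Rscript inst/cli/cfcea.R icer`, `... threshold --wtp
150000`, `... psa --n 10000 --seed 1`, etc.).

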