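---
title: "Model structure, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfcea)
```

## The decision problem

cfcea implements a Markov cohort state-transition model comparing two
strategies for people with cystic fibrosis who are homozygous for the F508del
CFTR mutation: usual care (antibiotics, pancreatic enzymes, aminoglycosides,
DNase) versus usual care plus the CFTR modulator combination
lumacaftor/ivacaftor. The perspective is a United States payer, outcomes are
discounted costs (2016 USD) and quality-adjusted life years (QALYs), and the
primary result is the incremental cost-effectiveness ratio (ICER) against a
willingness-to-pay benchmark of $150,000 per QALY.

The cohort moves among five states: mild (FEV1 percent predicted > 70),
moderate (40–70), severe (< 40), post-lung-transplant, and dead. Two
within-cycle transition events modify costs, utilities and routing:
pulmonary exacerbation (PE) and lung transplant. Cycles are one year; the
default horizon is ten years from a starting age of 12, with registry
severity splits at ages 6 (95/4/1), 12 (87/11/2) and 25 (46/37/17).

## The cycle event tree

Each cycle applies, in fixed order and identically in both arms:

1. a PE draw per live disease state (annual probabilities 0.3213 / 0.5748 /
   0.6794 for mild / moderate / severe);
2. PE-conditional death (0.001 in mild and moderate; 0.2174 in severe);
3. transplant among severe survivors (0.078, the same with and without PE),
   with transplant-year mortality 0.297 charged immediately;
4. disease progression (or, in the treatment arm's first cycle,
   improvement) among the remainder;
5. background CF mortality as a competing risk on all surviving
   disease-state occupants. Post-transplant occupants face only a
   years-since-transplant mortality schedule, and a transplant cannot be
   repeated.

The event ordering within a cycle is a modelling choice (the underlying
event tree is not fully ordered by its published description); because the
identical order is used in both arms, the incremental comparison is
internally consistent. Steps 2 and 5 treat PE mortality as additional to
background mortality.

Treatment effects have three components: a relative risk of 0.74 on the PE
probability, suspension of disease progression, and one-time improvement
transitions (moderate-to-mild 0.0935/0.1045 and severe-to-moderate
0.5517/0.5455, without/with PE) active only in the first treatment year.
Long-term effectiveness `e` blends the post-first-year dynamics linearly:
progression is scaled by `1 - e` and the effective relative risk is
`1 - e (1 - 0.74)`, so `e = 1` maintains the full effect (the base case) and
`e = 0` reverts to usual-care dynamics after year one (the worst case). The
first cycle always carries the full trial effect. Treatment is stopped at
transplant: post-transplant occupants accrue no drug cost and no treatment
effect.

## Accrual conventions

State rewards (annual state costs and utilities, and the treatment arm's
drug cost) accrue on start-of-cycle occupancy at stages `0..horizon`
inclusive; event rewards (PE cost and disutility, the one-time transplant
cost) accrue at each of the `horizon` transitions. This stage-inclusive
convention — an initial-state reward plus one reward per completed cycle —
is how the original implementation of this model counted cycles; it is the
only convention consistent with the published 10-year totals (with ten
accrual points the treated arm could not reach its published QALY total
even at full survival and mild-state utility). Setting
`options$terminal_accrual = FALSE` switches to plain `0..horizon-1`
accrual, and `options$half_cycle_correction = TRUE` half-weights the first
and terminal stage state rewards; both default to the published behaviour
(terminal accrual on, no half-cycle correction).

Further accrual choices, each made once and exposed as data rather than
code: the PE disutility (−0.17) applies for the entire cycle of the event;
drug cost is charged to every treated, alive, non-post-transplant occupant
for the full cycle, including those dying within it; the transplant's
one-time cost and transplant-year mortality are charged in the transition
cycle, while the higher first-year post-transplant maintenance cost begins
the following cycle; and multiple exacerbations per cycle are represented
by a multiplicative weight on PE costs (`costs$pe_weight`, default 1).

## Reconstructed inputs

Three inputs of the original model are not published numerically and are
reconstructed by the synthetic natural-history stage.

**Background CF mortality.** Only the 10-year cumulative usual-care
mortality (15.1%) is published. A flat annual hazard is solved by
root-finding so that the usual-care cohort, run through the full event
tree, reaches exactly that cumulative mortality
(`calibrate_background_hazard()`; the calibrated default is ≈ 0.0099 per
year). A flat hazard is used because only cumulative information exists;
the schedule object accepts arbitrary age-indexed values for users with a
life table. The same hazard is reused for the age-6 and age-25 scenarios,
which have no published mortality anchors — a known limitation, since CF
mortality rises with age, and one reason the age-25 scenario is the least
faithful reproduction (see below).

**Post-transplant mortality.** Only the transplant-year value (0.297) is
anchored. Later years use a declining tail, `0.10, 0.09, 0.08, 0.08, 0.07`
(last value recycled), shaped like published post-transplant survival in CF
(roughly 85–90% conditional survival in the year after the transplant
year, tapering toward 7% annual mortality). Post-transplant occupancy never
exceeds ~1% of the cohort, so results are insensitive to this tail.

**FEV1 decline rates.** The progression probabilities were originally
derived by bootstrapping a 1000-patient FEV1 cohort forward under
literature decline rates. `generate_fev1_cohort()` draws a normal cohort
(default mean 85, sd 14, clipped to [0, 150]), chosen so the share above
the mild cut-point (≈ 86%) approximates the registry split at age 12; a
single normal cannot simultaneously reproduce the 2% severe share, which
would require far more mass below 40. `calibrate_decline_rates()` finds the
with-PE/without-PE decline pair whose derived pooled progression
probabilities best match the four published values (0.0697 / 0.0307
mild-to-moderate, 0.0617 / 0.0279 moderate-to-severe). The objective is
piecewise constant in the rates (patients cross thresholds discretely), so
a deterministic two-stage grid search under common random numbers is used
instead of a simplex optimizer. Because the two-parameter generator cannot
drive all four targets to zero residual jointly (the moderate band of a
normal cohort holds too little mass near the 40% threshold), the stated
calibration tolerance is 0.05 RMS per probability; the parameter-recovery
property (planted rates recovered within 10% at n = 100,000) verifies the
estimator itself is consistent.

Because of this mismatch, the engine's default progression probabilities
are the published pooled point values themselves, not bootstrap output; the
bootstrap stage exists to document and test the derivation pathway, and
both per-age and pooled estimates are emitted for users who wish to
substitute them.

## What the synthetic stage does and does not emulate

The generator reproduces: a baseline FEV1 distribution with the correct
mild share, exacerbation-dependent annual decline, threshold
classification, and at-risk-based transition counting. It does not
reproduce: the true (skewed, age-dependent) FEV1 population distribution,
heterogeneous per-patient decline, or age-specific mortality and transplant
uptake. Tests passing against this stage therefore validate the package's
estimators and calibration machinery, not the epidemiological fidelity of
the synthetic cohort to real CF populations.

## Analyses

* `compute_icer()` reports incremental cost, incremental QALYs, their
  ratio, and standard dominance classification.
* `run_scenarios()` covers the published grid: horizons 2–10 years,
  long-term effectiveness 0/25/50/75/100%, starting ages 6/12/25, and a
  high-cost scenario (state costs ×4, PE costs replaced by the high
  published estimates — the replacement values are a documented calibration
  knob, defaulting to the upper one-way bounds).
* `threshold_drug_cost()` bisects on the annual drug price (tolerance
  $0.01); incremental QALYs are price-invariant and incremental cost is
  strictly increasing in price, so the root is unique. A willingness-to-pay
  below the zero-price ICER is reported as infeasible.
* `tornado()` recomputes the ICER at each parameter's published low/high
  bound (±20% where no range is published) and ranks by spread.
* `sample_psa()` draws parameters independently — beta for probabilities
  and utilities, gamma for costs, lognormal for the relative risk
  (published CI 0.592–0.89) — with one-way ranges read as 95% intervals,
  so `SE = (high − low)/3.92`, and all distributions moment-matched to the
  base-case mean. Calibrated schedules and the starting distribution are
  held fixed across draws. `ceac()` converts draws into an acceptability
  curve via net monetary benefit.

Problem sizes used by the packaged tests: deterministic runs at the full
10-year horizon; the brute-force path-enumeration cross-check at 1–3
cycles; parameter recovery at n = 100,000; the PSA consistency check at
n = 10,000 draws.

## Fidelity to the published results

With the packaged inputs the model reproduces the published 10-year totals
closely (usual-care cost within ~4%, treated cost and both QALY totals
within ~1.5%, base-case ICER within ~9%, age-6 scenario within ~10%).
Four published quantities are not reproducible within those margins under
any reconstruction we found consistent with the published inputs, and the
package reports its computed values rather than adjusting toward the
printed ones:

* the worst-case incremental QALY gain (published 0.20; computed ≈ 0.11):
  the published arm-wise death fractions (15.1% usual care, 12.6%
  worst-case, 11.0% treated) are not jointly attainable with any
  state-independent background hazard plus the published severe-PE
  mortality, and under identical post-year-one dynamics the one-year head
  start contracts rather than persisting undamped to year ten;
* the intermediate-effectiveness and age-25 ICERs, which inherit the same
  gap (the age-25 case additionally lacks its unpublished age-specific
  inputs);
* the threshold price (published $4153; computed ≈ $11,000): the ICER is
  exactly linear in the annual drug price, and the published threshold
  would require the treated arm's non-drug costs to exceed usual care by
  roughly $32,000 per patient, which contradicts a model in which
  treatment reduces exacerbation and progression costs. The computed
  threshold is the self-consistent solution for this model's own base
  case, and the package verifies the fixed-point identity
  `ICER(threshold_drug_cost(wtp)) = wtp` to solver tolerance.

`reproduce_results()` writes the full side-by-side comparison with
absolute and relative deviations.

## Numerical notes and degenerate inputs

Occupancy conservation (|Σ − 1| < 1e−9) and monotone death are asserted on
every run. Branch distributions are exhaustive by construction and checked
to 1e−12. A horizon of zero returns an empty trace with zero totals. A
target cumulative mortality below what the event tree alone produces is
reported as unreachable rather than silently clamped. Beta moment-matching
rejects variances incompatible with the (0, 1) support. Zero-width
uncertainty ranges degenerate to fixed draws. All stochastic stages take
explicit integer seeds and restore the caller's RNG state.
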