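---
title: "Methods: a decision-tree cost-effectiveness model for enhanced influenza vaccines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a decision-tree cost-effectiveness model for enhanced influenza vaccines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flucea)
```

## The decision problem

Adults aged 65 and over respond less well to standard-dose influenza
vaccines (immunosenescence), and two enhanced quadrivalent vaccines compete
for this population: a high-dose vaccine (HD-QIV) and an MF59-adjuvanted
vaccine (aQIV). No head-to-head trial compares them, the high-dose product
costs roughly twice as much per dose (EUR 32.27 vs EUR 15.45 to the Italian
NHS), and influenza's hospital burden is notoriously under-coded: admissions
carrying an influenza diagnosis code are a small fraction of the
cardiorespiratory admissions that influenza actually triggers. `flucea`
implements the full decision-analytic machinery needed to ask whether
switching a cohort of older adults from aQIV to HD-QIV is value for money
from a healthcare-payer perspective.

## Model structure

The engine is a one-season cohort decision tree evaluated in expectation
(`expected_arm_outcomes()`). For a cohort of size $N$ (the 65+ population
times the vaccination coverage), each arm $v$ produces:

* **Cases**: $N \cdot a \cdot (1 - f_c\,\mathrm{rVE}^v_c)$, where $a$ is the
  seasonal attack rate under the standard-dose comparator and $f_c$ an
  attenuation multiplier (below).
* **GP and emergency-room visits**: conditional on a case, with independent,
  non-mutually-exclusive probabilities — a patient can use both services.
* **Hospitalizations**, under one of two burden definitions:
  * *influenza-coded*: conditional on a case,
    $\text{cases} \cdot p_{hosp|case}$ — only admissions coded as influenza;
  * *cardiorespiratory* ("hidden burden"): a cohort-level admission rate
    scaled by the arm's efficacy against hospitalization,
    $N \cdot r_h \cdot (1 - f_h\,\mathrm{rVE}^v_h)$ — not conditioned on a
    coded case, because most influenza-attributable cardiorespiratory
    admissions are never coded as influenza
    (`attributable_admissions()` documents the motivating arithmetic:
    4,407 coded + 15,206 attributable admissions per year).
* **Deaths**: from the seasonal excess mortality rate $m$ per 100,000,
  proportional to the case burden the arm leaves unprevented:
  $N \cdot (m/10^5) \cdot s \cdot (1 - f_d\,\mathrm{rVE}^v_c)$, with
  $s$ (`risk_death_scale`) a configurable multiplier defaulting to 1.
  Because $f_d$ defaults to $f_c$, this is exactly "deaths scale with the
  cases averted"; exposing $f_d$ separately lets users encode a mortality
  channel steeper or shallower than the case channel.

All outputs are linear in the baseline rates, which is what makes exact
algebraic calibration possible (below).

### Indirect efficacy bridging

Each vaccine's efficacy is known only against the common standard-dose
comparator. Efficacy composes on the risk-ratio scale, so
`indirect_rve(a, b) = 1 - (1 - a)/(1 - b)`; a negative value (the
alternative worse than the reference) is legitimate and propagates, with
risks clamped to $[0,1]$. The published anchors are 24.2% (HD vs SD,
cases) and 18.2% (HD vs SD, cardiorespiratory hospitalization); aQIV vs SD
is scanned over scenarios 0% (base case), 6% and 12%
(`set_aqiv_scenario()`), applied to both outcomes unless a distinct
hospitalization value is supplied.

### The preventable-fraction multipliers

A trial-measured rVE against laboratory-confirmed influenza cannot act on
the whole clinically-attributed population burden (only a fraction of
clinical cases are lab-confirmable, attribution models overcount, coverage
is imperfect). The multipliers $f_c, f_h, f_d \in [0,1]$ make that
attenuation explicit: an arm's risk is `baseline * (1 - f * rVE)`. They
default to 1 (no attenuation); the shipped Italy-like fixture sets them so
that the fixture's population reductions match the published differential
columns ($f_c \approx 0.393$, $f_h \approx 0.506$).

## Valuation

Life-years and QALYs lost to premature death are valued over a lifetime
horizon; everything else happens within the season, so only death valuation
is discounted (3.0% per year, annual cycles, end-of-cycle convention, no
half-cycle correction — the simplest auditable convention for a model whose
comparisons are differences of identical baselines). `discounted_qale()`
computes
$LY(a) = \sum_t S(a,t)(1+r)^{-t}$ and the utility-weighted analogue using
age-specific population utilities. Deaths are valued at the cohort's
expected age (rounded to the grid): the excess-mortality input carries no
age split, and because both arms share the age distribution the choice
cancels almost entirely in the increments.

Acute events lose `(u_base - u_event) * duration/365` QALYs
(`episode_qaly_loss()`): 6 days at the influenza-episode utility per case
and 5.2 days at the hospitalized utility per admission. The two decrements
are additive for a hospitalized case; the durations are short enough that
the double-counted overlap is below every decision margin, but it is a
known divergence risk from conventions that substitute one decrement for
the other. Episode losses are undiscounted (they occur within the year).

## Economics

`arm_costs()` accumulates vaccine acquisition plus administration for the
whole cohort, visit costs, over-the-counter medication for *every* case
(deliberately conservative — it overstates the OTC offset symmetrically in
both arms), and admissions at the cardiorespiratory DRG tariff of
EUR 4,035.32. `incremental()` differences two arms per person and reports
ICER per LY and per QALY, the cost-effectiveness-plane quadrant, and net
monetary benefit $\mathrm{NMB} = \lambda\,\Delta Q - \Delta C$ at the
willingness-to-pay $\lambda$ (EUR 30,000/QALY by default). A negative ICER
is sign-ambiguous — it can mean "cheaper and better" or "costlier and
worse" — so the quadrant is always carried alongside, and SE/NW results are
labelled *Dominant*/*Dominated* rather than as bare ratios.

## Sensitivity analysis

* **One-way (tornado)**: each scalar parameter is pushed to its low/high
  bound (95% CI when supplied, otherwise mean ± 15%) with everything else
  at base case, and the pipeline reruns (`one_way_dsa()`). The tornado span
  is measured on incremental NMB at the base WTP for *every* entry: ICERs
  at different endpoints can sit in different quadrants, where their
  numeric order is meaningless, while NMB is linear and comparable
  throughout. Endpoint ICERs are still reported with dominance flags.
* **Probabilistic**: `run_psa()` redraws all parameters per iteration
  (1,000 iterations by default) and records per-person
  $(\Delta C, \Delta Q)$ pairs. Families follow standard health-economics
  convention — beta for probabilities and utilities, gamma for costs and
  other non-negative quantities, normal for efficacies — moment-matched
  from (mean, se) (`distribution_spec()`, `draw_parameters()`). The source
  analysis defers its distribution table to an earlier model publication
  that is not reproduced here, so the package states its own convention:
  default standard errors are set so the central 95% interval matches the
  ±15% deterministic range ($se = 0.15\,\mu/1.96$). Draws are clamped to
  type invariants with a reported clamp count; failed iterations are
  recorded, never fatal.
* **CEAC**: `ceac()` reports, per WTP value, the fraction of draws with
  strictly positive NMB; ties count as not cost-effective. The default grid
  is 0–100,000 in steps of 1,000.

## The synthetic parameter set

`default_italy_like()` is a complete, deterministic fixture for the Italian
setting. Printed anchors are fixed at their published values (the two HD
efficacies, scenario efficacies, durations, tariff, dose prices, discount
rate, WTP). The baseline epidemiology is *calibrated*, not asserted:
`calibrate_baseline()` inverts the linear tree so the aQIV arm under the
cardiorespiratory definition reproduces the published population outcome
column exactly (implying an attack rate of ≈9.1%, a GP-visit probability of
≈0.386, a cardiorespiratory admission rate of ≈5.9%, excess mortality of
≈75.8/100,000 for a cohort of 13.9M × 58.2% coverage ≈ 8.09M people).

The remaining fields are documented fixtures, chosen once for plausibility,
and are *not* estimates of the original supplementary inputs: a
Gompertz-like life table over ages 65–100 with a closed terminal age,
a geometrically declining age distribution (mean ≈ 75), population
utilities declining linearly from 0.89 to 0.75 across the grid, an
influenza-episode utility of 0.50 and in-hospital utility of 0.35, GP/ER
unit costs of EUR 20.66/241.77, and EUR 5 of OTC medication per case.
`sample_parameter_set()` jitters exactly the unprinted fields
(multiplicative log-uniform, clamped to invariants) for property-style
testing.

Consequences worth stating plainly: the fixture reproduces the anchored
aQIV column and the published *differential* hospitalization/case columns,
and HD-QIV is dominant under the cardiorespiratory definition, as
published. It does **not** reproduce the published per-person cost totals
or headline ICERs (EUR 7,301/9,805/14,733), which depend on the
supplementary input table: on this fixture the influenza-coded ICERs are
higher (≈24,000–49,000 EUR/QALY) because the fixture's death channel
follows the case channel ($f_d = f_c$), averting ≈580 deaths where the
publication reports 1,820 — a reduction its printed efficacies alone cannot
produce from fields constrained to $[0,1]$. Passing tests therefore
demonstrate the correctness of the machinery (exact differencing, exact
calibration, oracle agreement, orderings and dominance logic), not
agreement with unpublished inputs.

## Numerical and testing choices

* The expectation engine is the analysis path; an individual-level
  Bernoulli simulator (`simulate_arm_outcomes()`) exists purely as an
  independent oracle, checked to within 3 binomial standard errors at
  n = 200,000 simulated individuals.
* Property suites run at deliberately modest sizes — 1,000 jittered
  parameter sets for the validity property, 50,000 draws for
  moment-matching checks, 1,000 PSA iterations in the acceptance script —
  chosen to make sampling error negligible relative to the asserted
  tolerances.
* Calibration refuses targets implying probabilities above 1 and names the
  infeasible quantity; degenerate inputs (zero attack rate, zero spread,
  self-comparison) are exercised in tests and return exact zeros rather
  than NaNs.
* Quadrant boundaries: axis points fold into the adjacent weak-dominance
  quadrant; the origin is "none". The antisymmetry NE↔SW, SE↔NW under arm
  swapping is tested.

## Limitations

Static model: no herd immunity, no within-season dynamics, no waning, no
age-structured transmission. Payer perspective only: no productivity
losses or out-of-pocket costs. Long-term consequences beyond the LY/QALY
loss of premature death are excluded. The cardiorespiratory definition
inherits the uncertainty of statistical attribution — the true
influenza-attributable share of those admissions is unknown, and with it
the realism of that scenario's savings.
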