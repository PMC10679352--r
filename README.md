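# flucea

Decision-analytic cost-effectiveness modelling of enhanced seasonal
influenza vaccines — high-dose (HD-QIV) versus MF59-adjuvanted (aQIV)
quadrivalent vaccines — in adults aged 65 and over, from a healthcare-payer
perspective.

The package is aimed at health-economics analysts who need a transparent,
fully tested implementation of the standard vaccine cost-effectiveness
toolkit: a one-season cohort decision tree with lifetime-discounted
life-year/QALY losses for premature death, indirect efficacy bridging
through a common comparator, two hospitalization-burden definitions,
incremental analysis (ICER, net monetary benefit, dominance), and
deterministic plus probabilistic sensitivity analysis.

## The model in brief

For a cohort of size *N* (65+ population × coverage), each vaccine arm *v*
generates expected events

- cases = *N* · *a* · (1 − *f_c* · rVE<sub>v,cases</sub>)
- GP / ER visits, conditional on a case (independent, non-exclusive)
- hospitalizations: either conditional on an influenza-coded case, or a
  cohort-level cardiorespiratory admission rate scaled by
  (1 − *f_h* · rVE<sub>v,hosp</sub>) — the "hidden burden" definition
- deaths = *N* · (excess mortality / 10⁵) · (1 − *f_d* · rVE<sub>v,cases</sub>)

where efficacies against the standard-dose comparator combine indirectly on
the risk-ratio scale, rVE<sub>A vs B</sub> = 1 − (1 − rVE<sub>A</sub>)/(1 −
rVE<sub>B</sub>). Costs are accumulated per arm; health outcomes are valued
as discounted life-years and QALYs (3% per year, annual cycles) with
short-term utility decrements for episodes and admissions. Strategies are
compared by ICER = ΔC/ΔQ with its cost-effectiveness-plane quadrant, and
NMB = WTP · ΔQ − ΔC at a willingness-to-pay of €30,000/QALY.

See `vignettes/cost-effectiveness-model.Rmd` for the full account of the
model, its parameters, conventions and limitations.

## Worked example

```r
library(flucea)

params <- default_italy_like()        # Italy-like fixture, printed anchors fixed
params$scenario$hospitalization_approach <- "cardiorespiratory"

aqiv <- expected_arm_outcomes(params, "aQIV")
hd   <- expected_arm_outcomes(params, "HD-QIV")
incremental(aqiv, hd, wtp = 30000)
#> <flucea_incremental> HD-QIV vs aQIV
#>   dCost -5.1430 EUR | dLY 0.000762 | dQALY 0.000715 (per person)
#>   ICER Dominant EUR/QALY | quadrant SE | NMB 26.58 EUR at WTP 30,000
```

Switching the ~8.09M-person cohort to the high-dose vaccine averts 69,987
influenza cases, 43,771 cardiorespiratory admissions (saving
43,771 × €4,035.32 ≈ €176 million in hospitalization costs alone) and,
despite the €16.82 price gap per dose, lowers total payer cost by €5.14 per
person while gaining 0.0007 QALYs — the high-dose strategy *dominates*
(cheaper and more effective). Under the stricter influenza-coded
hospitalization definition the switch is no longer cost-saving and the
ICER rises with the efficacy assumed for the adjuvanted comparator:

```r
params$scenario$hospitalization_approach <- "influenza_coded"
sapply(c(0, 0.06, 0.12), function(sc)
  run_comparison(set_aqiv_scenario(params, sc))$icer_per_qaly)
#> [1] 24370.36 32569.72 48834.01   # EUR per QALY, aQIV rVE 0% / 6% / 12%
```

A full run — scenario tables, tornado, PSA draws and the acceptability
curve as figure-ready CSVs — is one call:

```r
run_analysis(params = default_italy_like(), approach = "cardiorespiratory",
             scenarios = c(0, 0.06, 0.12), psa_n = 1000, seed = 1,
             outdir = "out")
```

or from the shell via the bundled wrapper
`inst/cli/run_analysis.R` (`--config`, `--approach`, `--scenario`,
`--psa-n`, `--seed`, `--wtp`, `--no-dsa`, `--outdir`).

A ready-made configuration file ships at
`inst/extdata/italy_default.yaml`; `load_parameter_set()` /
`write_parameter_set()` roundtrip it losslessly and validate every field.

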