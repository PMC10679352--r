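#' Indirect relative vaccine efficacy through a common comparator
#'
#' When two vaccines A and B have each been compared only against a common
#' comparator C (here the standard-dose vaccine), their relative efficacy is
#' bridged on the risk-ratio scale:
#' \deqn{rVE_{A vs B} = 1 - \frac{1 - rVE_{A vs C}}{1 - rVE_{B vs C}}}
#' The result may be negative when B outperforms A; that is meaningful and is
#' propagated downstream (risks may increase, clamped at 1).
#'
#' @param rve_a_vs_c relative efficacy of vaccine A versus the comparator,
#'   as a proportion (0.242 means 24.2\%).
#' @param rve_b_vs_c relative efficacy of vaccine B versus the comparator;
#'   must be strictly below 1.
#' @return The indirect relative efficacy of A versus B (proportion).
#' @examples
#' indirect_rve(0.242, 0)     # 0.242: B no better than comparator
#' indirect_rve(0.242, 0.06)  # 1 - 0.758/0.94
#' @export
indirect_rve <- function(rve_a_vs_c, rve_b_vs_c) {
  if (any(rve_b_vs_c >= 1))
    stop("rve_b_vs_c must be < 1: comparison versus the common comparator ",
         "is undefined at 100% efficacy", call. = FALSE)
  1 - (1 - rve_a_vs_c) / (1 - rve_b_vs_c)
}

#' Apply relative efficacy to a baseline risk
#'
#' Scales a per-person seasonal risk under the comparator vaccine by
#' `1 - f * rVE`, where `f` is a preventable-fraction attenuation multiplier
#' in \[0,1\] (the fraction of the population burden that the measured
#' efficacy can act on, e.g. the laboratory-confirmable share of clinical
#' cases). The result is clamped to \[0,1\]; a negative `rve_vs_sd` (vaccine
#' worse than comparator) raises the risk.
#'
#' @param baseline_risk per-person seasonal probability under the comparator.
#' @param rve_vs_sd relative efficacy versus the comparator (may be negative).
#' @param preventable_fraction attenuation multiplier in \[0,1\]; default 1.
#' @return The arm-specific probability.
#' @examples
#' arm_risk(0.05, 0.242)       # 0.05 * 0.758
#' arm_risk(0.05, 0.242, 0)    # fully attenuated: baseline unchanged
#' @export
arm_risk <- function(baseline_risk, rve_vs_sd, preventable_fraction = 1) {
  stopifnot(all(baseline_risk >= 0 & baseline_risk <= 1),
            all(preventable_fraction >= 0 & preventable_fraction <= 1))
  pmin(pmax(baseline_risk * (1 - preventable_fraction * rve_vs_sd), 0), 1)
}

# Arm-specific risk multipliers relative to the standard-dose baseline.
# Returns list(risk_cases, risk_hosp, death_ratio): per-person probabilities
# of a case / (cardiorespiratory) hospitalization and the mortality ratio
# versus the SD baseline.
.arm_profile <- function(params, arm) {
  ef <- params$efficacy
  rve <- switch(arm,
    "HD-QIV" = list(cases = ef$rve_hd_vs_sd_cases,
                    hosp  = ef$rve_hd_vs_sd_hosp),
    "aQIV"   = list(cases = ef$rve_aqiv_vs_sd_cases,
                    hosp  = ef$rve_aqiv_vs_sd_hosp),
    "SD-QIV" = list(cases = 0, hosp = 0),
    stop("unknown arm label: '", arm,
         "' (expected 'HD-QIV', 'aQIV' or 'SD-QIV')", call. = FALSE)
  )
  list(
    arm_label = arm,
    risk_cases = arm_risk(params$epi$attack_rate, rve$cases,
                          ef$preventable_fraction_cases),
    risk_hosp = arm_risk(params$epi$cardioresp_hosp_rate, rve$hosp,
                         ef$preventable_fraction_hosp),
    # mortality scales with the case burden averted; f_deaths attenuates the
    # case efficacy on the death channel and risk_death_scale is a further
    # configurable multiplier (default 1)
    death_ratio = ef$risk_death_scale *
      arm_risk(1, rve$cases, ef$preventable_fraction_deaths)
  )
}
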