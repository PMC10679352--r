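# Small fast fixture: 1M cohort, short life table, round probabilities.
# `...` overrides are dotted paths, e.g. tiny_params("epi.attack_rate" = 0).
tiny_params <- function(...) {
  ages <- 65:75
  surv <- c(rep(0.97, 10), 0)   # closed terminal age
  bu <- setNames(seq(0.85, 0.75, length.out = 11), ages)
  w <- setNames(rep(1 / 11, 11), ages)
  p <- parameter_set(
    efficacy = list(rve_hd_vs_sd_cases = 0.242, rve_hd_vs_sd_hosp = 0.182,
                    rve_aqiv_vs_sd_cases = 0),
    epi = list(cohort_size = 1e6, attack_rate = 0.05, p_gp_given_case = 0.4,
               p_er_given_case = 0.1, p_hosp_influenza_given_case = 0.06,
               cardioresp_hosp_rate = 0.04, excess_mortality_per_100k = 80,
               coverage = 0.5),
    costs = list(price_aqiv = 15.45, price_hd = 32.27, cost_gp_visit = 20,
                 cost_er_visit = 240, cost_hospitalization = 4035.32,
                 cost_otc_per_case = 5),
    utilities = list(baseline_utility_by_age = bu,
                     utility_influenza_episode = 0.5,
                     utility_hospitalized = 0.35,
                     influenza_duration_days = 6,
                     hospitalization_duration_days = 5.2),
    life_table = list(ages = ages, annual_survival_prob = surv,
                      discount_rate = 0.03),
    age_distribution = w
  )
  overrides <- list(...)
  for (path in names(overrides)) p <- param_set(p, path, overrides[[path]])
  p
}
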