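test_that("expected event counts follow the tree arithmetic", {
  p <- tiny_params("epi.p_gp_given_case" = 0.4,
                   "efficacy.rve_hd_vs_sd_cases" = 0,
                   "efficacy.rve_hd_vs_sd_hosp" = 0)
  out <- expected_arm_outcomes(p, "HD-QIV")
  expect_equal(out$population$cases, 1e6 * 0.05, tolerance = 1e-12)
  expect_equal(out$population$gp_visits, 20000, tolerance = 1e-12)
  expect_equal(out$population$er_visits, 5000, tolerance = 1e-12)
  expect_equal(out$population$hospitalizations, 50000 * 0.06,
               tolerance = 1e-12)
  expect_error(expected_arm_outcomes(p, "XD-QIV"), "unknown arm")
})

test_that("an attack rate of zero empties the tree", {
  p <- tiny_params("epi.attack_rate" = 0,
                   "epi.cardioresp_hosp_rate" = 0,
                   "epi.excess_mortality_per_100k" = 0)
  for (arm in c("aQIV", "HD-QIV")) {
    out <- expected_arm_outcomes(p, arm)
    expect_identical(out$population$cases, 0)
    expect_identical(out$population$gp_visits, 0)
    expect_identical(out$population$er_visits, 0)
    expect_identical(out$population$hospitalizations, 0)
    expect_identical(out$population$deaths, 0)
    price <- if (arm == "HD-QIV") 32.27 else 15.45
    expect_equal(out$per_person$total_cost, price + p$costs$admin_cost,
                 tolerance = 1e-9)
  }
})

test_that("identical efficacy gives identical outcomes up to vaccine cost", {
  p <- tiny_params("efficacy.rve_hd_vs_sd_cases" = 0.1,
                   "efficacy.rve_hd_vs_sd_hosp" = 0.1,
                   "efficacy.rve_aqiv_vs_sd_cases" = 0.1,
                   "efficacy.rve_aqiv_vs_sd_hosp" = 0.1)
  a <- expected_arm_outcomes(p, "aQIV")
  h <- expected_arm_outcomes(p, "HD-QIV")
  for (f in c("cases", "gp_visits", "er_visits", "hospitalizations",
              "deaths", "lys", "qalys")) {
    expect_equal(h$population[[f]], a$population[[f]], tolerance = 1e-12)
  }
  expect_equal(h$population$total_cost - a$population$total_cost,
               1e6 * (32.27 - 15.45), tolerance = 1e-6)
})

test_that("population outputs scale linearly with cohort size and respect
           internal consistency", {
  p1 <- tiny_params()
  p2 <- param_set(p1, "epi.cohort_size", 3e6)
  for (arm in c("aQIV", "HD-QIV")) {
    o1 <- expected_arm_outcomes(p1, arm)
    o2 <- expected_arm_outcomes(p2, arm)
    for (f in names(o1$population)) {
      expect_equal(o2$population[[f]], 3 * o1$population[[f]],
                   tolerance = 1e-9)
    }
    # count invariants
    expect_lte(o1$population$gp_visits, o1$population$cases)
    expect_lte(o1$population$er_visits, o1$population$cases)
    expect_lte(o1$population$hospitalizations, o1$population$cases)
    # per-person and population views agree
    expect_equal(o1$per_person$total_cost * o1$cohort_size,
                 o1$population$total_cost, tolerance = 1e-9)
    expect_equal(o1$per_person$qalys * o1$cohort_size,
                 o1$population$qalys, tolerance = 1e-9)
  }
})

test_that("hidden-burden hospitalizations drop under positive indirect
           efficacy", {
  p <- tiny_params()
  p$scenario$hospitalization_approach <- "cardiorespiratory"
  a <- expected_arm_outcomes(p, "aQIV")
  h <- expected_arm_outcomes(p, "HD-QIV")
  expect_gt(indirect_rve(p$efficacy$rve_hd_vs_sd_hosp,
                         p$efficacy$rve_aqiv_vs_sd_hosp), 0)
  expect_lt(h$population$hospitalizations, a$population$hospitalizations)
})

test_that("Monte-Carlo simulation agrees with the expectation engine", {
  n <- 200000
  for (approach in c("influenza_coded", "cardiorespiratory")) {
    p <- tiny_params()
    p$scenario$hospitalization_approach <- approach
    exp_out <- expected_arm_outcomes(p, "HD-QIV")
    sim <- simulate_arm_outcomes(p, "HD-QIV", n, seed = 7)
    # determinism given the seed
    sim2 <- simulate_arm_outcomes(p, "HD-QIV", n, seed = 7)
    expect_identical(sim$population, sim2$population)

    scale <- p$epi$cohort_size / n
    for (f in c("cases", "gp_visits", "er_visits", "hospitalizations",
                "deaths")) {
      mu <- exp_out$population[[f]]
      pr <- mu / p$epi$cohort_size           # marginal per-person probability
      se <- sqrt(n * pr * (1 - pr)) * scale  # binomial SE on the pop scale
      expect_lt(abs(sim$population[[f]] - mu), 3 * se + 1e-9,
                label = sprintf("%s/%s deviation", approach, f))
    }
  }
})

test_that("simulation with a zero attack rate produces no events", {
  p <- tiny_params("epi.attack_rate" = 0, "epi.cardioresp_hosp_rate" = 0,
                   "epi.excess_mortality_per_100k" = 0)
  for (seed in c(1, 99)) {
    sim <- simulate_arm_outcomes(p, "aQIV", 5000, seed = seed)
    expect_identical(sim$population$cases, 0)
    expect_identical(sim$population$deaths, 0)
  }
})

test_that("coded plus hidden admissions sum to the attributable total", {
  expect_identical(attributable_admissions(4407, 15206), 19613)
  expect_identical(attributable_admissions(123, 0), 123)
  expect_identical(attributable_admissions(0, 0), 0)
  expect_error(attributable_admissions(-1, 0))
})
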