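test_that("cost breakdown components sum and scale linearly", {
  costs <- tiny_params()$costs
  ev <- list(cohort_size = 1e6, cases = 50000, gp_visits = 20000,
             er_visits = 5000, hospitalizations = 3000)
  cb <- arm_costs(ev, costs, arm = "aQIV")
  expect_equal(cb$total,
               cb$vaccine + cb$gp + cb$er + cb$otc + cb$hospitalization,
               tolerance = 1e-9)
  expect_equal(cb$vaccine, 1e6 * (15.45 + costs$admin_cost),
               tolerance = 1e-9)
  expect_equal(cb$hospitalization, 3000 * 4035.32, tolerance = 1e-9)

  # zero events: vaccine cost only
  ev0 <- list(cohort_size = 1e6, cases = 0, gp_visits = 0, er_visits = 0,
              hospitalizations = 0)
  cb0 <- arm_costs(ev0, costs, arm = "HD-QIV")
  expect_equal(cb0$total, 1e6 * (32.27 + costs$admin_cost),
               tolerance = 1e-9)

  # doubling events doubles every non-vaccine component
  ev2 <- lapply(ev, `*`, 2); ev2$cohort_size <- ev$cohort_size
  cb2 <- arm_costs(ev2, costs, arm = "aQIV")
  for (f in c("gp", "er", "otc", "hospitalization")) {
    expect_equal(cb2[[f]], 2 * cb[[f]], tolerance = 1e-9)
  }
  expect_equal(cb2$vaccine, cb$vaccine, tolerance = 1e-9)
})

# Minimal arm built directly from per-person figures.
manual_arm <- function(label, cost_pp, ly_pp, qaly_pp, cohort = 1e6) {
  arm_outcomes(label,
               population = list(cases = 0, gp_visits = 0, er_visits = 0,
                                 hospitalizations = 0, deaths = 0,
                                 total_cost = cost_pp * cohort,
                                 lys = ly_pp * cohort,
                                 qalys = qaly_pp * cohort),
               cohort_size = cohort)
}

test_that("ICER, quadrant and NMB follow the incremental arithmetic", {
  ref <- manual_arm("aQIV", 100, 10, 9)
  alt <- manual_arm("HD-QIV", 110, 10.002, 9.001)
  inc <- incremental(ref, alt, wtp = 30000)
  expect_equal(inc$delta_cost, 10, tolerance = 1e-9)
  expect_equal(inc$icer_per_qaly, 10 / 0.001, tolerance = 1e-6)
  expect_identical(inc$quadrant, "NE")
  expect_equal(inc$nmb_at_wtp, 30000 * 0.001 - 10, tolerance = 1e-6)

  # published per-person inputs: NMB at 30,000 EUR/QALY
  inc2 <- incremental(manual_arm("aQIV", 15.44, 10.2447, 8.8905),
                      manual_arm("HD-QIV", 15.44 + 8.67, 10.2460,
                                 8.8905 + 0.00118), wtp = 30000)
  expect_equal(inc2$nmb_at_wtp, 26.73, tolerance = 1e-6)

  # dominant: cheaper and more effective
  incd <- incremental(manual_arm("aQIV", 153.82, 10.2447, 8.8899),
                      manual_arm("HD-QIV", 149.90, 10.2460, 8.8912))
  expect_identical(incd$quadrant, "SE")
  expect_identical(incd$icer_label, "Dominant")

  # equal effect, different cost: cost-minimization verdict
  incm <- incremental(manual_arm("aQIV", 100, 10, 9),
                      manual_arm("HD-QIV", 120, 10, 9))
  expect_true(is.na(incm$icer_per_qaly))
  expect_identical(incm$quadrant, "NW")
})

test_that("self-comparison is null and swapping arms mirrors the result", {
  a <- manual_arm("aQIV", 100, 10, 9)
  self <- incremental(a, a)
  expect_identical(self$delta_cost, 0)
  expect_identical(self$delta_qaly, 0)
  expect_identical(self$quadrant, "none")

  b <- manual_arm("HD-QIV", 95, 10.01, 9.02)
  ab <- incremental(a, b); ba <- incremental(b, a)
  expect_equal(ab$delta_cost, -ba$delta_cost, tolerance = 1e-12)
  expect_equal(ab$delta_qaly, -ba$delta_qaly, tolerance = 1e-12)
  mirror <- c(NE = "SW", SE = "NW", NW = "SE", SW = "NE")
  expect_identical(unname(mirror[ab$quadrant]), ba$quadrant)
})

test_that("positive NMB coincides with cost-effectiveness by quadrant", {
  set.seed(11)
  wtp <- 30000
  for (i in 1:300) {
    dc <- runif(1, -50, 50); dq <- runif(1, -0.005, 0.005)
    inc <- incremental(manual_arm("aQIV", 100, 10, 9),
                       manual_arm("HD-QIV", 100 + dc, 10, 9 + dq), wtp)
    ce <- switch(inc$quadrant,
      SE = TRUE, NW = FALSE,
      NE = inc$icer_per_qaly < wtp,
      SW = inc$icer_per_qaly > wtp,
      none = FALSE)
    expect_identical(inc$nmb_at_wtp > 0, ce)
  }
})

test_that("the summary table carries the documented shape and labels", {
  inc <- incremental(manual_arm("aQIV", 15.44, 10.2447, 8.8905),
                     manual_arm("HD-QIV", 24.11, 10.2460, 8.9023))
  tab <- incremental_table(inc)
  expect_identical(tab$outcome, c("Total costs", "Total LYs", "Total QALYs"))
  expect_identical(names(tab), c("outcome", "aQIV", "HD-QIV", "incremental",
                                 "icer"))
  expect_identical(tab$incremental[1], "8.67")
})
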