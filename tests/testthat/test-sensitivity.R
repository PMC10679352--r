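test_that("parameter draws match requested moments and are reproducible", {
  specs <- list(
    distribution_spec("epi.attack_rate", "beta", mean = 0.3, se = 0.05),
    distribution_spec("costs.cost_gp_visit", "gamma", mean = 20, se = 3),
    distribution_spec("efficacy.rve_hd_vs_sd_cases", "normal",
                      mean = 0.242, se = 0.02)
  )
  tab <- draw_parameters(specs, n = 50000, seed = 3)
  expect_identical(tab, draw_parameters(specs, n = 50000, seed = 3))
  expect_lt(abs(mean(tab$`epi.attack_rate`) - 0.3), 0.005)
  expect_lt(abs(sd(tab$`epi.attack_rate`) - 0.05), 0.005)
  expect_lt(abs(mean(tab$`costs.cost_gp_visit`) - 20), 0.1)
  expect_lt(abs(sd(tab$`costs.cost_gp_visit`) - 3), 0.1)
  expect_lt(abs(mean(tab$`efficacy.rve_hd_vs_sd_cases`) - 0.242), 0.001)

  # zero se collapses every family to a point mass
  pt <- draw_parameters(list(
    distribution_spec("epi.attack_rate", "beta", mean = 0.3, se = 0),
    distribution_spec("costs.cost_gp_visit", "gamma", mean = 20, se = 0)
  ), n = 10, seed = 1)
  expect_true(all(pt$`epi.attack_rate` == 0.3))
  expect_true(all(pt$`costs.cost_gp_visit` == 20))

  expect_error(distribution_spec("epi.attack_rate", "beta", mean = 0.3,
                                 se = 0.5), "se too large")
  expect_error(distribution_spec("epi.attack_rate", "beta", mean = 1.3,
                                 se = 0.1), "\\[0,1\\]")
})

test_that("a degenerate PSA equals the deterministic incremental result", {
  p <- tiny_params()
  det <- run_comparison(p)
  specs <- default_distribution_specs(p, rel = 0)  # all point masses
  psa <- run_psa(p, specs = specs, n = 5, seed = 1)
  expect_identical(length(psa$failures), 0L)
  expect_true(all(abs(psa$draws$delta_cost - det$delta_cost) < 1e-12))
  expect_true(all(abs(psa$draws$delta_qaly - det$delta_qaly) < 1e-12))

  # continuity: a vanishing spread concentrates on the deterministic value
  psa_eps <- run_psa(p, specs = default_distribution_specs(p, rel = 1e-6),
                     n = 50, seed = 2)
  expect_lt(abs(mean(psa_eps$draws$delta_cost) - det$delta_cost), 1e-3)
  expect_lt(abs(mean(psa_eps$draws$delta_qaly) - det$delta_qaly), 1e-6)
})

test_that("PSA results are reproducible per seed", {
  p <- tiny_params()
  a <- run_psa(p, n = 20, seed = 5)
  b <- run_psa(p, n = 20, seed = 5)
  expect_identical(a$draws, b$draws)
  expect_false(identical(a$draws, run_psa(p, n = 20, seed = 6)$draws))
})

test_that("the acceptability curve is the NMB exceedance fraction", {
  # single point-mass draw: a step from 0 to 1 at dC/dQ
  psa1 <- structure(list(n_draws = 1, seed = 1,
                         draws = data.frame(delta_cost = 8.67,
                                            delta_qaly = 0.00118),
                         failures = list(), n_clamped = 0L),
                    class = "flucea_psa")
  step <- 8.67 / 0.00118
  cv <- ceac(psa1, wtp_grid = c(0, floor(step), ceiling(step), 100000))
  expect_identical(cv$prob_cost_effective, c(0, 0, 1, 1))
  # ties count as not cost-effective (strict NMB > 0); exact binary values
  psat <- psa1
  psat$draws <- data.frame(delta_cost = 4, delta_qaly = 0.5)
  expect_identical(ceac(psat, wtp_grid = 8)$prob_cost_effective, 0)

  # all-dominant draws are cost-effective at every threshold
  psad <- structure(list(n_draws = 3, seed = 1,
                         draws = data.frame(delta_cost = c(-1, -2, -0.5),
                                            delta_qaly = c(1e-3, 2e-3, 5e-4)),
                         failures = list(), n_clamped = 0L),
                    class = "flucea_psa")
  expect_true(all(ceac(psad)$prob_cost_effective == 1))

  # monotone non-decreasing whenever every draw gains QALYs
  psa <- run_psa(tiny_params(), n = 30, seed = 9)
  if (all(psa$draws$delta_qaly > 0)) {
    cv2 <- ceac(psa)
    expect_true(all(diff(cv2$prob_cost_effective) >= 0))
  }
})

test_that("tornado entries rerun the pipeline and sort by NMB span", {
  p <- tiny_params()
  # administration cost hits both arms identically: an inert parameter
  ranges <- list(
    param_range("efficacy.rve_hd_vs_sd_cases", 0.15, 0.35),
    param_range("costs.cost_hospitalization", 4035.32 * 0.85,
                4035.32 * 1.15),
    param_range("costs.admin_cost", 0, 10)
  )
  tt <- one_way_dsa(p, ranges = ranges)
  expect_s3_class(tt, "flucea_tornado")
  expect_true(all(diff(tt$span) <= 0))
  inert <- tt[tt$parameter == "costs.admin_cost", ]
  expect_equal(inert$span, 0, tolerance = 1e-9)
  expect_identical(tt$parameter[nrow(tt)], "costs.admin_cost")

  # span is invariant to the order in which ranges are supplied
  tt_rev <- one_way_dsa(p, ranges = rev(ranges))
  expect_equal(tt$span, tt_rev$span, tolerance = 1e-12)
  expect_identical(tt$parameter, tt_rev$parameter)
})

test_that("default ranges span mean plus/minus 15 percent", {
  p <- tiny_params()
  rgs <- default_dsa_ranges(p)
  by_par <- setNames(rgs, vapply(rgs, `[[`, character(1), "parameter"))
  rg <- by_par[["costs.cost_hospitalization"]]
  expect_equal(rg$low, 4035.32 * 0.85, tolerance = 1e-9)
  expect_equal(rg$high, 4035.32 * 1.15, tolerance = 1e-9)
})

test_that("higher efficacy against hospitalization lowers the ICER", {
  p <- tiny_params("epi.cardioresp_hosp_rate" = 0.01)
  p$scenario$hospitalization_approach <- "cardiorespiratory"
  grid <- seq(0.05, 0.30, length.out = 5)
  nmb <- icer <- numeric(5)
  for (i in seq_along(grid)) {
    inc <- run_comparison(param_set(p, "efficacy.rve_hd_vs_sd_hosp",
                                    grid[i]))
    icer[i] <- inc$icer_per_qaly
    nmb[i] <- inc$nmb_at_wtp
  }
  expect_true(all(diff(nmb) > 0))
  ne <- icer[icer > 0]  # comparable while still in the NE quadrant
  expect_true(all(diff(ne) < 0))
})
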