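test_that("growth matches the closed form on planted energy-coupled toys", {
  # boundary: pump exactly covers maintenance -> growth 0 but feasible
  toy <- make_toy_fba_model(ppr = 4, ngam = 1, k = 4, a = 10)
  sol <- maximize_growth(toy$model)
  expect_identical(sol$status, "optimal")
  expect_equal(sol$growth_rate, 0, tolerance = 1e-9)
  # interior optimum
  toy2 <- make_toy_fba_model(ppr = 8, ngam = 1, k = 4, a = 10)
  expect_equal(maximize_growth(toy2$model)$growth_rate, 0.1,
               tolerance = 1e-9)
  # pump below the maintenance threshold -> infeasible
  toy3 <- make_toy_fba_model(ppr = 3.9, ngam = 1, k = 4)
  expect_identical(maximize_growth(toy3$model)$status, "infeasible")
})

test_that("PPR sweep records growth per grid point and the threshold", {
  sw <- sweep_ppr(core_model_cached(),
                  scenario_config("rtca", ngam = 8.39),
                  grid = seq(30, 40, by = 0.5))
  expect_equal(attr(sw, "threshold"), 34.0)
  expect_true(all(sw$growth[!sw$feasible] == 0))
  expect_true(all(diff(sw$growth) >= -1e-9))
  # no maintenance -> growth possible from the first grid point
  sw0 <- sweep_ppr(core_model_cached(),
                   scenario_config("rtca", ngam = 0),
                   grid = seq(0, 2, by = 0.5))
  expect_equal(attr(sw0, "threshold"), 0)
  expect_error(sweep_ppr(core_model_cached(), scenario_config("rtca"),
                         grid = numeric(0)), "empty")
  expect_error(sweep_ppr(core_model_cached(), scenario_config("rtca"),
                         grid = c(5, 1)), "sorted")
})

test_that("growth is monotone in the PPR bound and anti-monotone in NGAM", {
  grow <- function(ngam, ppr) {
    sm <- build_scenario(core_model_cached(),
                         scenario_config("calvin", ngam = ngam,
                                         ppr_upper_bound = ppr))
    s <- maximize_growth(sm)
    if (s$status == "optimal") s$growth_rate else 0
  }
  by_ppr <- vapply(c(10, 20, 35, 50), function(p) grow(1, p), numeric(1))
  expect_true(all(diff(by_ppr) >= -1e-9))
  by_ngam <- vapply(c(0, 1, 4, 8.39), function(n) grow(n, 50), numeric(1))
  expect_true(all(diff(by_ngam) <= 1e-9))
})

test_that("steady-state mass balance holds at every pathway optimum", {
  for (pw in c("rtca", "calvin", "hp4hb")) {
    run <- scenario_solution(pw)
    expect_lt(mass_balance_residual(run$sm, run$sol), 1e-8)
  }
})

test_that("flux variability reports degeneracy on a parallel-branch toy and
           uniqueness of the scenario exchange fluxes", {
  toy <- make_toy_branch_model(supply = 5)
  fva <- flux_variability(toy$model, reactions = c("T1", "T2"))
  expect_true(all(fva$variable))
  expect_equal(fva$min_flux, c(0, 0), tolerance = 1e-6)
  expect_equal(fva$max_flux, c(5, 5), tolerance = 1e-6)
  # pinning growth to 0 lets the coupled fluxes collapse to 0
  fva0 <- flux_variability(toy$model, fixed_growth = 0,
                           reactions = c("T1", "T2"))
  expect_equal(fva0$min_flux, c(0, 0), tolerance = 1e-6)
  # CO2 and electron exchange are unique at the scenario optimum
  run <- scenario_solution("rtca")
  fvx <- flux_variability(run$sm, fixed_growth = run$sol$growth_rate,
                          reactions = c("EX_ee", "EX_co2_e"))
  expect_false(any(fvx$variable))
})

test_that("uptake summary and proton balance summarize the rTCA optimum", {
  run <- scenario_solution("rtca")
  up <- uptake_summary(run$sol)
  expect_equal(up$ppr_flux, 50, tolerance = 1e-6)
  expect_gt(up$electron_uptake, 0)
  expect_gt(up$co2_uptake, 0)
  pb <- proton_balance(run$sol, run$sm)
  # conservation: all membrane proton fluxes cancel
  expect_equal(pb$net, 0, tolerance = 1e-8)
  # synthase influx exceeds the pumped efflux; the gap is medium protons
  expect_gt(pb$atp_synthase_influx,
            pb$ppr_efflux + pb$quinol_linked_efflux)
  expect_gt(pb$quinol_linked_efflux, 0)  # ubiquinol recovery pumps protons
  # infeasible solutions are rejected
  bad <- maximize_growth(make_toy_fba_model(ppr = 0, ngam = 1)$model)
  expect_error(uptake_summary(bad), "optimal")
  expect_error(proton_balance(bad, run$sm), "optimal")
})
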