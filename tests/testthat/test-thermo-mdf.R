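RT <- 8.314e-3 * 298.15

test_that("closed-form optima of tiny concentration problems", {
  # one reaction, dG0 = 0, both ends free over 4 decades:
  # B = RT ln(1e4) = 22.83 kJ/mol
  th <- data.frame(reaction_id = "R1", equation = "1 a -> 1 b",
                   drg0_prime = 0, se = 0)
  res <- mdf(th, constraints = NULL)
  expect_equal(res$mdf, RT * log(1e4), tolerance = 1e-6)
  expect_identical(res$bottlenecks, "R1")
  # two identical reactions split the range evenly: RT ln(1e2) each
  th2 <- data.frame(reaction_id = c("R1", "R2"),
                    equation = c("1 a -> 1 x", "1 x -> 1 b"),
                    drg0_prime = 0, se = 0)
  res2 <- mdf(th2, constraints = NULL)
  expect_equal(res2$mdf, RT * log(1e2), tolerance = 1e-6)
  expect_setequal(res2$bottlenecks, c("R1", "R2"))
  # concentrations cancel when substrate and product are pinned equal
  th3 <- data.frame(reaction_id = "R1", equation = "1 a -> 1 b",
                    drg0_prime = -10, se = 0)
  res3 <- mdf(th3, constraints = rbind(conc_fixed("a", 1e-3),
                                       conc_fixed("b", 1e-3)))
  expect_equal(res3$mdf, 10, tolerance = 1e-9)
  # a hugely endergonic reaction cannot be rescued by the range
  th4 <- data.frame(reaction_id = "R1", equation = "1 a -> 1 b",
                    drg0_prime = 100, se = 0)
  expect_lt(mdf(th4, constraints = NULL)$mdf, 0)
})

test_that("invariants: each concentration in range, ratios exact, minimum
           driving force equals the optimum", {
  th <- thermo_table("rtca")
  res <- mdf(th)
  expect_equal(min(res$driving_forces), res$mdf, tolerance = 1e-6)
  lnc <- res$ln_concentrations
  free <- setdiff(names(lnc), c("co2", "hco3", "pi", "ppi", "coa"))
  expect_true(all(lnc[free] >= log(1e-6) - 1e-9))
  expect_true(all(lnc[free] <= log(1e-2) + 1e-9))
  expect_equal(lnc[["co2"]], log(3e-4), tolerance = 1e-9)
  expect_equal(lnc[["nadh"]] - lnc[["nad"]], log(0.1), tolerance = 1e-9)
  expect_equal(lnc[["fdrd"]] - lnc[["fdox"]], log(10), tolerance = 1e-9)
})

test_that("LP agrees with brute-force grid search on seeded toy chains", {
  for (seed in 1:100) {
    toy <- make_toy_thermo_pathway(3, seed = seed)
    res <- mdf(toy$thermo, constraints = toy$constraints)
    brute <- brute_mdf_chain(toy$thermo, log(1e-2), log(1e-6))
    expect_equal(res$mdf, brute, tolerance = 0.05,
                 label = paste("seed", seed))
  }
})

test_that("monotonicity: wider ranges and relaxed ratios never hurt", {
  th <- thermo_table("calvin")
  base <- mdf(th)$mdf
  wide <- mdf(th, conc_range = c(1e-7, 1e-1))$mdf
  expect_gte(wide + 1e-9, base)
  # adding a ratio constraint (on top of free members) cannot increase MDF
  th2 <- data.frame(reaction_id = c("R1", "R2"),
                    equation = c("1 a + 1 nadh -> 1 x + 1 nad",
                                 "1 x -> 1 b"),
                    drg0_prime = c(5, 0), se = 0)
  unconstrained <- mdf(th2, constraints = NULL)$mdf
  tied <- mdf(th2, constraints = conc_ratio("nadh", "nad", 0.1))$mdf
  expect_lte(tied, unconstrained + 1e-9)
})

test_that("energy-uncertainty slack never lowers the optimum", {
  for (pw in pathway_names()) {
    th <- thermo_table(pw)
    plain <- mdf(th, use_uncertainty = FALSE)$mdf
    slack <- mdf(th, use_uncertainty = TRUE)$mdf
    expect_gte(slack + 1e-9, plain)
    # shifts stay within one standard error
    res <- mdf(th, use_uncertainty = TRUE)
    expect_true(all(abs(res$shifts) <= th$se + 1e-9))
  }
})

test_that("reactions are taken exactly as written (no rescaling)", {
  th <- data.frame(reaction_id = "R1", equation = "1 a -> 1 b",
                   drg0_prime = 0, se = 0)
  th_scaled <- data.frame(reaction_id = "R1", equation = "2 a -> 2 b",
                          drg0_prime = 0, se = 0)
  a <- mdf(th, constraints = NULL)$mdf
  b <- mdf(th_scaled, constraints = NULL)$mdf
  expect_equal(b, 2 * a, tolerance = 1e-6)  # doubled stoichiometry doubles
  expect_false(isTRUE(all.equal(a, b)))     # the drive: not normalized away
})

test_that("infeasible constraint systems raise a named error", {
  th <- data.frame(reaction_id = "R1", equation = "1 a -> 1 b",
                   drg0_prime = 0, se = 0)
  cons <- rbind(conc_fixed("a", 1e-3),
                conc_ratio("a", "b", 10),
                conc_fixed("b", 1e-3))
  expect_error(mdf(th, constraints = cons), "infeasible")
})

test_that("sensitivity sweeps reproduce the base point and behave
           monotonically on a toy", {
  res_base <- mdf(thermo_table("rtca"), use_uncertainty = TRUE)
  sweep <- mdf_sensitivity("rtca", "fd_ratio", grid = 10,
                           use_uncertainty = TRUE)
  expect_equal(sweep$mdf, res_base$mdf, tolerance = 1e-6)
  # toy A -> B with A fixed: raising fixed [B] lowers the MDF linearly
  th <- data.frame(reaction_id = "R1", equation = "1 a -> 1 b",
                   drg0_prime = -10, se = 0)
  vals <- vapply(c(1e-5, 1e-4, 1e-3), function(bconc)
    mdf(th, constraints = rbind(conc_fixed("a", 1e-3),
                                conc_fixed("b", bconc)))$mdf,
    numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_equal(vals[1] - vals[2], RT * log(10), tolerance = 1e-6)
  expect_error(mdf_sensitivity("rtca", "temperature"), "unknown sensitivity")
})

test_that("lowering the ferredoxin pool potential strains the rTCA cycle", {
  sweep <- mdf_sensitivity("rtca", "fd_ratio", grid = c(0.5, 10),
                           use_uncertainty = TRUE)
  expect_lt(sweep$mdf[1], 4.0)
  expect_gt(sweep$mdf[2], sweep$mdf[1])
})
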