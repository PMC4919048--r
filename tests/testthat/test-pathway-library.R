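test_that("pathway enzyme counts match the published characteristics", {
  counts <- c(calvin = 12, rtca = 8, hp4hb = 13, dc4hb = 14,
              pyrs_pyrc_glx = 10, pyrs_pepc_glx = 11)
  for (pw in names(counts)) {
    def <- get_pathway(pw)
    expect_equal(def$enzyme_count, unname(counts[pw]), label = pw)
    # the declared count equals the number of distinct cycle enzymes
    cyc <- def$reactions[def$reactions$in_cycle, ]
    expect_equal(length(unique(cyc$enzyme)), unname(counts[pw]), label = pw)
    expect_identical(def$end_product, "pyr_c")
    expect_equal(def$n_carbons_per_product, 3)
  }
  expect_error(get_pathway("wood_ljungdahl"), "valid tokens")
})

test_that("carboxylation species follow the pathway definitions", {
  # Calvin's carboxylase consumes CO2, not bicarbonate
  calvin <- get_pathway("calvin")$reactions
  rbpc <- parse_equation(calvin$equation[calvin$id == "RBPC"])$stoich
  expect_lt(rbpc[["co2_c"]], 0)
  expect_false("hco3_c" %in% names(rbpc))
  # the 3HP-4HB variant assimilates acetyl-CoA through pyruvate synthase
  hp <- get_pathway("hp4hb")
  expect_true("PYRS" %in% hp$reactions$id)
  expect_false(hp$reactions$in_cycle[hp$reactions$id == "PYRS"])
  # ferredoxin-coupled reactions consume reduced ferredoxin
  pyrs <- parse_equation(
    hp$reactions$equation[hp$reactions$id == "PYRS"])$stoich
  expect_equal(pyrs[["fdxrd_c"]], -2)
})

test_that("energy module has PPR, electron exchange and regeneration only", {
  em <- energy_module_reactions()
  expect_setequal(em$id, c("PPR", "EX_ee", "FDR", "NADPHR"))
  ppr <- parse_equation(em$equation[em$id == "PPR"])$stoich
  expect_equal(ppr, c(h_c = -1, h_e = 1))
  nadphr <- parse_equation(em$equation[em$id == "NADPHR"])$stoich
  expect_equal(nadphr[["e_e"]], -2)
  expect_equal(nadphr[["h_c"]], -1)
  fdr <- parse_equation(em$equation[em$id == "FDR"])$stoich
  expect_equal(fdr[["e_e"]], -1)
  # no reaction regenerates NADH directly from electrons
  for (eq in em$equation) {
    st <- parse_equation(eq)$stoich
    expect_false("nadh_c" %in% names(st)[st > 0])
  }
})

test_that("every reaction is elementally balanced for carbon", {
  core <- core_model_cached()
  pw_mets <- utils::read.delim(
    system.file("extdata", "pathway_metabolites.tsv", package = "carbfix"),
    na.strings = character(0))
  carbon <- c(stats::setNames(core$mets$carbon, core$mets$id),
              stats::setNames(carbfix:::count_carbon(pw_mets$formula),
                              pw_mets$id))
  for (pw in pathway_names()) {
    rx <- get_pathway(pw)$reactions
    for (i in seq_len(nrow(rx))) {
      st <- parse_equation(rx$equation[i])$stoich
      expect_equal(sum(st * carbon[names(st)]), 0,
                   label = paste(pw, rx$id[i], "carbon balance"))
    }
  }
})

test_that("each pathway fixes 3 carbons and 10 electrons per pyruvate", {
  for (pw in pathway_names()) {
    sm <- build_scenario(core_model_cached(),
                         scenario_config(pw, ngam = 0, ppr_upper_bound = 1000))
    model <- set_bounds(sm$model, sm$model$biomass_id, lb = 0, ub = 0)
    model <- add_reaction(model, "DM_pyr", "1 pyr_c ->")
    model$biomass_id <- "DM_pyr"
    sm$model <- model
    sol <- maximize_growth(sm)
    expect_identical(sol$status, "optimal")
    v_pyr <- sol$growth_rate
    expect_gt(v_pyr, 1)
    up <- uptake_summary(sol)
    expect_equal(up$co2_uptake / v_pyr, 3, tolerance = 1e-6, label = pw)
    expect_equal(up$electron_uptake / v_pyr, 10, tolerance = 1e-6,
                 label = pw)
  }
})

test_that("thermodynamic annotations cover each pathway at each grid pH", {
  for (pw in pathway_names()) {
    def <- get_pathway(pw)
    th <- thermo_table(pw)
    expect_true(all(th$se >= 0))
    expect_gte(nrow(th), def$enzyme_count)
    expect_equal(anyDuplicated(th$reaction_id), 0)
  }
  th75 <- thermo_table("rtca", ph = 7.5)
  th90 <- thermo_table("rtca", ph = 9.0)
  # carboxylations shift with pH by the first-order proton-release slope
  RT <- 8.314e-3 * 298.15
  d <- th90$drg0_prime - th75$drg0_prime
  expect_equal(d[th90$reaction_id == "PYRS"], RT * log(10) * 1.5,
               tolerance = 1e-9)
  expect_error(thermo_table("rtca", ph = 7.25), "no thermodynamic fixture")
})

test_that("calvin GAPD electron donor is NADH by default, NADPH by flag", {
  th <- thermo_table("calvin")
  expect_match(th$equation[th$reaction_id == "GAPD"], "nadh")
  th2 <- thermo_table("calvin", gapd_nadph = TRUE)
  expect_match(th2$equation[th2$reaction_id == "GAPD"], "nadph")
})

test_that("fixture specific activities equal the trimmed aggregate of the
           packaged observation collections", {
  obs <- activity_observations()
  kin <- kinetics_table("rtca")
  for (i in seq_len(nrow(obs))) {
    j <- kin$reaction_id == obs$reaction_id[i]
    if (!any(j)) next
    expect_equal(kin$specific_activity[j],
                 aggregate_specific_activity(obs$values[[i]]),
                 label = obs$reaction_id[i])
    expect_gt(kin$n_observations[j], 0)
  }
  # hand-checked collection: pyruvate synthase aggregates to 10
  pyrs <- obs$values[[which(obs$reaction_id == "PYRS")]]
  expect_equal(aggregate_specific_activity(pyrs), 10)
})
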