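test_that("equation parser handles coefficients, reversibility and errors", {
  p <- parse_equation("1 a + 2 b -> 1 c")
  expect_equal(p$stoich, c(a = -1, b = -2, c = 1))
  expect_false(p$reversible)
  expect_true(parse_equation("x <-> y")$reversible)
  # exchange with one side empty
  expect_equal(parse_equation("1 co2_e ->")$stoich, c(co2_e = -1))
  expect_error(parse_equation("a = b"), "malformed")
  expect_error(parse_equation("->"), "empty stoichiometry")
})

test_that("the packaged core network has the published structure", {
  m <- core_model_cached()
  expect_equal(nrow(m$rxns), 95)
  expect_equal(nrow(m$mets), 72)
  # ATP synthase translocates 4 medium protons per ATP
  expect_equal(unname(m$S["h_e", "ATPS4r"]), -4)
  expect_equal(unname(m$S["atp_c", "ATPS4r"]), 1)
  # biomass consumes the growth-associated maintenance ATP
  expect_equal(unname(-m$S["atp_c", "Biomass_Ecoli_core"]), 59.81)
  # every stoichiometry entry references a declared metabolite by layout
  expect_setequal(rownames(m$S), m$mets$id)
  # carbon counts come from the formulas
  expect_equal(m$mets$carbon[m$mets$id == "glc__D_e"], 6)
  expect_equal(m$mets$carbon[m$mets$id == "co2_e"], 1)
})

test_that("SBML round-trip preserves stoichiometry and bounds", {
  m <- core_model_cached()
  f <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, f)
  m2 <- read_model(f)
  expect_setequal(m2$rxns$id, m$rxns$id)
  expect_equal(m2$S[rownames(m$S), colnames(m$S)], m$S)
  expect_equal(m2$rxns$lb[match(m$rxns$id, m2$rxns$id)], m$rxns$lb)
  expect_equal(m2$rxns$ub[match(m$rxns$id, m2$rxns$id)], m$rxns$ub)
  expect_identical(m2$biomass_id, "Biomass_Ecoli_core")
})

test_that("tiny hand-written SBML parses; broken files raise format errors", {
  one <- c(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="4">',
    '<model id="mini"><listOfCompartments><compartment id="c"/></listOfCompartments>',
    '<listOfSpecies>',
    '<species id="M_a_c" name="A" compartment="c"/>',
    '<species id="M_b_c" name="B" compartment="c"/>',
    '</listOfSpecies><listOfReactions>',
    '<reaction id="R_biomass_conv" reversible="true">',
    '<listOfReactants><speciesReference species="M_a_c" stoichiometry="1"/></listOfReactants>',
    '<listOfProducts><speciesReference species="M_b_c" stoichiometry="1"/></listOfProducts>',
    '<kineticLaw><listOfParameters>',
    '<parameter id="LOWER_BOUND" value="-10"/><parameter id="UPPER_BOUND" value="10"/>',
    '</listOfParameters></kineticLaw></reaction>',
    '</listOfReactions></model></sbml>')
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(one, f)
  m <- read_sbml(f)
  expect_equal(nrow(m$rxns), 1)
  expect_equal(nrow(m$mets), 2)
  expect_equal(m$rxns$lb, -10)
  expect_equal(m$rxns$ub, 10)

  # reaction referencing an undeclared species
  bad <- sub("M_b_c(?=.*Products)", "M_ghost_c", one, perl = TRUE)
  bad <- gsub('species="M_b_c"', 'species="M_ghost_c"', one)
  f2 <- withr::local_tempfile(fileext = ".xml")
  writeLines(bad, f2)
  expect_error(read_sbml(f2), "undeclared species 'M_ghost_c'")

  # not XML at all
  f3 <- withr::local_tempfile(fileext = ".xml")
  writeLines("this is not xml <", f3)
  expect_error(read_sbml(f3), "parse failure")

  # no biomass reaction identifiable
  noobj <- gsub("R_biomass_conv", "R_conv", one)
  f4 <- withr::local_tempfile(fileext = ".xml")
  writeLines(noobj, f4)
  expect_error(read_sbml(f4), "no biomass objective")
})

test_that("result tables render with shared keys and 3 significant digits", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_result_table(data.frame(pathway = "rTCA cycle", growth = 0.208792),
                     f)
  lines <- readLines(f)
  expect_length(lines, 2)
  expect_identical(lines[1], "pathway\tgrowth")
  expect_identical(lines[2], "rTCA cycle\t0.209")

  # empty table -> header only
  write_result_table(data.frame(a = numeric(0), b = numeric(0)), f)
  expect_identical(readLines(f), "a\tb")

  # mismatched keys across records
  expect_error(
    write_result_table(list(list(a = 1, b = 2), list(a = 1, c = 3)), f),
    "mismatched keys")
})

test_that("model validation catches malformed input", {
  mets <- data.frame(id = c("a", "b"), name = c("a", "b"),
                     compartment = c("c", "c"), formula = "")
  rxns <- data.frame(id = "r1", name = "r1", lower = 5, upper = -5,
                     equation = "1 a -> 1 b")
  expect_error(model_from_tables(mets, rxns), "lower bound above upper")
  rxns2 <- data.frame(id = "r1", name = "r1", lower = 0, upper = 1,
                      equation = "1 a -> 1 ghost")
  expect_error(model_from_tables(mets, rxns2), "undeclared metabolite")
  mets$compartment <- c("c", "periplasm")
  rxns3 <- data.frame(id = "r1", name = "r1", lower = 0, upper = 1,
                      equation = "1 a -> 1 b")
  expect_error(model_from_tables(mets, rxns3), "unrecognized compartment")
})
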