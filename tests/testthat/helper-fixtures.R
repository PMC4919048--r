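# Shared small fixtures for the tests.

# append one reaction to an existing model
add_reaction <- function(model, id, equation, lb = 0, ub = 1000,
                         name = id) {
  st <- parse_equation(equation)$stoich
  stopifnot(all(names(st) %in% rownames(model$S)))
  S <- cbind(model$S, 0)
  colnames(S)[ncol(S)] <- id
  S[names(st), id] <- st
  rxns <- rbind(model$rxns[c("id", "name", "lb", "ub")],
                data.frame(id = id, name = name, lb = lb, ub = ub))
  metabolic_model(model$mets, rxns, S,
                  biomass_id = model$biomass_id, ngam_id = model$ngam_id)
}

# tiny ATP-accounting model: CO2 -> X (1 ATP) -> P (AMP-forming, 2 ATP)
toy_atp_model <- function(with_atp = TRUE) {
  mets <- data.frame(
    id = c("co2_c", "x_c", "p_c", "atp_c", "adp_c", "amp_c"),
    name = c("CO2", "intermediate", "product", "ATP", "ADP", "AMP"),
    compartment = "c",
    formula = c("CO2", "CH2O", "CH2O2", "C10H12N5O13P3", "C10H12N5O10P2",
                "C10H12N5O7P"),
    stringsAsFactors = FALSE)
  rxns <- data.frame(
    id = c("EX_co2", "R1", "R2", "DM_p", "REGEN1", "REGEN2"),
    name = c("CO2 exchange", "carboxylation", "AMP-forming step",
             "product sink", "ADP rephosphorylation",
             "AMP rephosphorylation"),
    lower = c(-10, 0, 0, 0, 0, 0),
    upper = c(0, 1000, 1000, 1000, 1000, 1000),
    equation = c(
      "1 co2_c <->",
      if (with_atp) "1 atp_c + 1 co2_c -> 1 adp_c + 1 x_c"
      else "1 co2_c -> 1 x_c",
      if (with_atp) "1 atp_c + 1 x_c -> 1 amp_c + 1 p_c"
      else "1 x_c -> 1 p_c",
      "1 p_c ->",
      "1 adp_c -> 1 atp_c",
      "1 amp_c -> 1 atp_c"),
    stringsAsFactors = FALSE)
  model_from_tables(mets, rxns, biomass_id = "DM_p")
}

core_model_cached <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- load_core_model()
    m
  }
})

scenario_solution <- local({
  cache <- list()
  function(pathway, ngam = 1.00, ppr = 50) {
    key <- paste(pathway, ngam, ppr, sep = "|")
    if (is.null(cache[[key]])) {
      sm <- build_scenario(core_model_cached(),
                           scenario_config(pathway, ngam = ngam,
                                           ppr_upper_bound = ppr))
      cache[[key]] <<- list(sm = sm, sol = maximize_growth(sm))
    }
    cache[[key]]
  }
})
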