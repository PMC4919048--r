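## Scenario assembly: core network + missing pathway reactions + PPR +
## electron uptake, under anaerobic autotrophic constraints.

#' Assemble a photo-electro-autotrophic scenario model
#'
#' Extends a base (core) model with the chosen fixation pathway's missing
#' reactions, the PPR proton pump and the electron-uptake module, then
#' applies the scenario constraints: oxygen and glucose exchanges closed
#' (anaerobic, autotrophic), CO2 exchange open in both directions, electron
#' exchange and the NADPH/ferredoxin regeneration reactions unconstrained,
#' the PPR capped at \code{scenario$ppr_upper_bound}, the ATP maintenance
#' lower bound at \code{scenario$ngam}, and (optionally) every exchange of a
#' carbon-containing metabolite other than CO2 closed so that no reduced
#' by-product can be secreted. Pathway-specific knockouts (the succinyl-CoA
#' ligase removal that forces flux through the full 3HP-4HB arm) and bound
#' widenings (reversible isocitrate lyase for the glyoxylate-assimilating
#' bicycles) are applied from the pathway definition.
#'
#' @param base a \code{metabolic_model}, typically [load_core_model()].
#' @param scenario a [scenario_config()]; \code{pathway_name = "none"}
#'   installs only the energy module.
#' @return object of class \code{scenario_model}: list with \code{model},
#'   \code{scenario}, \code{added_reaction_ids}, \code{blocked_exchange_ids}.
#' @export
#' @examples
#' sm <- build_scenario(load_core_model(), scenario_config("rtca"))
#' sm$model
build_scenario <- function(base, scenario) {
  stopifnot(inherits(base, "metabolic_model"),
            inherits(scenario, "scenario_config"))
  pw_rx <- energy_module_reactions()
  knockouts <- character(0)
  if (scenario$pathway_name != "none") {
    pw <- get_pathway(scenario$pathway_name)
    pw_rx <- rbind(pw_rx, pw$reactions[names(pw_rx)])
    knockouts <- pw$knockouts
  }

  reuse <- pw_rx$id[pw_rx$action == "reuse"]
  missing_native <- setdiff(reuse, base$rxns$id)
  if (length(missing_native) > 0L)
    stop("base model lacks native reaction(s) required by the pathway: ",
         paste(missing_native, collapse = ", "))

  add <- pw_rx[pw_rx$action == "add" & !pw_rx$id %in% base$rxns$id, ,
               drop = FALSE]
  ## metabolites introduced by the added reactions
  pw_mets <- read_fixture("pathway_metabolites.tsv")
  used <- unique(unlist(lapply(add$equation,
                               function(e) names(parse_equation(e)$stoich))))
  new_mets <- pw_mets[pw_mets$id %in% setdiff(used, base$mets$id), ,
                      drop = FALSE]
  unknown <- setdiff(used, c(base$mets$id, new_mets$id))
  if (length(unknown) > 0L)
    stop("pathway reactions reference unknown metabolite(s): ",
         paste(unknown, collapse = ", "))

  mets <- rbind(base$mets[c("id", "name", "compartment", "formula")],
                new_mets[c("id", "name", "compartment", "formula")])
  rxns <- rbind(base$rxns[c("id", "name", "lb", "ub")],
                data.frame(id = add$id, name = add$enzyme,
                           lb = add$lower, ub = add$upper,
                           stringsAsFactors = FALSE))
  S <- matrix(0, nrow(mets), nrow(rxns),
              dimnames = list(mets$id, rxns$id))
  S[rownames(base$S), colnames(base$S)] <- base$S
  for (j in seq_len(nrow(add))) {
    st <- parse_equation(add$equation[j])$stoich
    S[names(st), add$id[j]] <- st
  }
  model <- metabolic_model(mets, rxns, S,
                           biomass_id = base$biomass_id,
                           ngam_id = base$ngam_id)

  ## widen bounds (e.g. reversible ICL) and knockouts
  for (i in which(pw_rx$action == "widen"))
    model <- set_bounds(model, pw_rx$id[i],
                        lb = pw_rx$lower[i], ub = pw_rx$upper[i])
  for (ko in knockouts)
    model <- set_bounds(model, ko, lb = 0, ub = 0)

  ## anaerobic autotrophic medium
  for (ex in c("EX_o2_e", "EX_glc__D_e"))
    if (ex %in% model$rxns$id) model <- set_bounds(model, ex, lb = 0, ub = 0)
  model <- set_bounds(model, "EX_co2_e", lb = -1000, ub = 1000)
  model <- set_bounds(model, "PPR", lb = 0, ub = scenario$ppr_upper_bound)
  model <- apply_ngam(model, scenario$ngam)

  blocked <- character(0)
  if (scenario$block_byproducts) {
    for (ex in exchange_reactions(model)) {
      met <- rownames(model$S)[model$S[, ex] != 0]
      if (met == "co2_e") next
      if (model$mets$carbon[model$mets$id == met] > 0) {
        model <- set_bounds(model, ex, lb = 0, ub = 0)
        blocked <- c(blocked, ex)
      }
    }
  }
  structure(list(model = model, scenario = scenario,
                 added_reaction_ids = add$id,
                 blocked_exchange_ids = blocked),
            class = "scenario_model")
}

#' @export
print.scenario_model <- function(x, ...) {
  cat("<scenario_model> pathway '", x$scenario$pathway_name,
      "', NGAM ", x$scenario$ngam, ", PPR <= ",
      x$scenario$ppr_upper_bound, "\n", sep = "")
  cat("  added: ", paste(x$added_reaction_ids, collapse = ", "), "\n",
      sep = "")
  if (length(x$blocked_exchange_ids) > 0L)
    cat("  blocked exchanges: ",
        length(x$blocked_exchange_ids), " carbon by-products\n", sep = "")
  invisible(x)
}
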