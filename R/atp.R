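## ATP accounting: ATP consumed per biomass precursor along the FBA-active
## routes from inorganic carbon, and total ATP per gram biomass.

## currency metabolites never carry embodied ATP cost
CURRENCY_METS <- c("atp_c", "adp_c", "amp_c", "nad_c", "nadh_c", "nadp_c",
                   "nadph_c", "coa_c", "q8_c", "q8h2_c", "h_c", "h_e",
                   "h2o_c", "h2o_e", "pi_c", "pi_e", "ppi_c", "nh4_c",
                   "nh4_e", "e_e", "fdxox_c", "fdxrd_c", "o2_c", "o2_e")
## inorganic carbon enters at zero cost
SOURCE_METS <- c("co2_c", "co2_e", "hco3_c")

#' The twelve biomass precursors of the core network
#' @return character vector of metabolite ids.
#' @export
core_precursors <- function() {
  c("g6p_c", "f6p_c", "e4p_c", "r5p_c", "g3p_c", "3pg_c",
    "pep_c", "pyr_c", "accoa_c", "oaa_c", "glu__L_c", "gln__L_c")
}

## carbons carried by a metabolite for cost allocation: the CoA moiety
## (21 C) of thioesters is catalytic and excluded
skeletal_carbon <- function(model) {
  carbon <- model$mets$carbon
  names(carbon) <- model$mets$id
  thio <- grepl("coa_c$", names(carbon)) & names(carbon) != "coa_c"
  carbon[thio] <- pmax(carbon[thio] - 21, 0)
  carbon
}

## net ATP equivalents spent by one unit of (oriented) reaction flux:
## ATP -> ADP counts 1, ATP -> AMP counts 2, ATP regenerated counts -1
atp_equivalents_of <- function(stoich) {
  s_atp <- if ("atp_c" %in% names(stoich)) stoich[["atp_c"]] else 0
  s_amp <- if ("amp_c" %in% names(stoich)) stoich[["amp_c"]] else 0
  -s_atp + s_amp
}

#' ATP cost per biomass precursor along the active flux routes
#'
#' Traces the ATP embodied in each precursor from inorganic carbon through
#' the reactions that carry flux in the FBA solution. Every active reaction
#' (|flux| > \code{tol}, oriented by flux sign; exchanges and the biomass
#' reaction excluded) passes the cost of its carbon substrates plus its own
#' ATP expenditure to its carbon products, allocated by carbon share (CoA
#' moieties excluded); AMP-forming steps count 2 ATP; ATP regenerated by
#' substrate-level phosphorylation on a route is netted off. Metabolites
#' produced by several active reactions receive the flux-weighted mean
#' cost. Cycles are handled implicitly: the allocation equations of a cycle
#' couple and resolve to its per-turn net ATP stoichiometry.
#'
#' @param sol optimal \code{flux_solution}.
#' @param sm the \code{scenario_model} it came from.
#' @param precursors metabolite ids to report (default [core_precursors()]).
#' @param tol activity threshold on |flux|.
#' @param check_unique if \code{TRUE}, run flux variability on the active
#'   precursor-producing reactions first and raise an ambiguity error when
#'   any of them admits alternative flux at the optimum.
#' @return named numeric vector of mmol ATP per mmol precursor.
#' @export
precursor_atp_costs <- function(sol, sm, precursors = core_precursors(),
                                tol = 1e-6, check_unique = FALSE) {
  if (!inherits(sol, "flux_solution") || sol$status != "optimal")
    stop("precursor_atp_costs() needs an optimal flux solution")
  model <- as_model(sm)
  carbon <- skeletal_carbon(model)
  active <- which(abs(sol$fluxes) > tol &
                    model$rxns$id != model$biomass_id &
                    !model$rxns$id %in% exchange_reactions(model))
  if (isTRUE(check_unique)) {
    prod_rxns <- model$rxns$id[active][vapply(active, function(j)
      any(model$S[precursors, j] * sign(sol$fluxes[j]) > 0), logical(1))]
    fva <- flux_variability(sm, fixed_growth = sol$growth_rate,
                            reactions = prod_rxns)
    if (any(fva$variable))
      stop("ambiguous routes: alternative optima through ",
           paste(fva$id[fva$variable], collapse = ", "))
  }

  is_traced <- function(ids) ids[!ids %in% c(CURRENCY_METS, SOURCE_METS) &
                                   carbon[ids] > 0]
  mets <- character(0)
  for (j in active) {
    s <- model$S[, j]
    mets <- union(mets, is_traced(rownames(model$S)[s != 0]))
  }
  if (length(mets) == 0L)
    return(stats::setNames(rep(NA_real_, length(precursors)), precursors))
  idx <- stats::setNames(seq_along(mets), mets)
  n <- length(mets)
  W <- matrix(0, n, n)          # inflow coefficients
  wsum <- rep(0, n)             # total producing flux weight
  bvec <- rep(0, n)
  for (j in active) {
    sgn <- sign(sol$fluxes[j])
    v <- abs(sol$fluxes[j])
    s <- model$S[, j] * sgn
    s <- s[s != 0]
    prods <- is_traced(names(s)[s > 0])
    if (length(prods) == 0L) next
    subs <- is_traced(names(s)[s < 0])
    K <- sum(s[prods] * carbon[prods])
    if (K <= 0) next
    a <- atp_equivalents_of(s)
    for (p in prods) {
      i <- idx[[p]]
      w <- v * s[[p]]
      share <- carbon[[p]] / K
      wsum[i] <- wsum[i] + w
      bvec[i] <- bvec[i] + w * share * a
      for (sb in subs)
        W[i, idx[[sb]]] <- W[i, idx[[sb]]] + w * share * (-s[[sb]])
    }
  }
  produced <- wsum > tol
  M <- diag(wsum[produced]) - W[produced, produced, drop = FALSE]
  cost <- rep(NA_real_, n)
  cost[produced] <- solve(M, bvec[produced])
  names(cost) <- mets
  out <- stats::setNames(rep(NA_real_, length(precursors)), precursors)
  hit <- precursors %in% mets
  out[hit] <- cost[precursors[hit]]
  out
}

#' Total ATP per gram biomass
#'
#' Combines per-precursor ATP costs with the precursor stoichiometry of the
#' biomass reaction and adds the growth-associated maintenance read from
#' the ATP coefficient of that reaction.
#'
#' @param costs named vector from [precursor_atp_costs()].
#' @param sm scenario (or metabolic) model providing the biomass reaction.
#' @param gam growth-associated maintenance (mmol ATP/gCDW); default: the
#'   ATP consumed by the biomass reaction itself.
#' @return total mmol ATP/gCDW.
#' @export
total_atp_per_biomass <- function(costs, sm, gam = NULL) {
  model <- as_model(sm)
  bm <- model$S[, model$biomass_id]
  if (is.null(gam)) {
    if (!"atp_c" %in% rownames(model$S) || bm["atp_c"] >= 0)
      stop("biomass reaction consumes no ATP; supply gam explicitly")
    gam <- -bm[["atp_c"]]
  }
  miss <- names(costs)[is.na(match(names(costs), rownames(model$S))) |
                         bm[names(costs)] >= 0]
  if (length(miss) > 0L)
    stop("precursor(s) not consumed by the biomass reaction: ",
         paste(miss, collapse = ", "))
  known <- !is.na(costs)
  sum(costs[known] * (-bm[names(costs)[known]])) + gam
}
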