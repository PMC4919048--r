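## Flux balance analysis, flux variability, PPR sweeps and flux summaries.

lp_from_model <- function(model, obj_id, maximize = TRUE) {
  obj <- as.numeric(model$rxns$id == obj_id)
  list(obj = obj, A = model$S, b = rep(0, nrow(model$S)),
       lb = model$rxns$lb, ub = model$rxns$ub, maximize = maximize)
}

as_model <- function(x) {
  if (inherits(x, "scenario_model")) x$model
  else if (inherits(x, "metabolic_model")) x
  else stop("expected a scenario_model or metabolic_model")
}

#' Maximize growth by flux balance analysis
#'
#' Solves \eqn{\max v_{biomass}} subject to \eqn{S v = 0} and the flux
#' bounds. Status is \code{"infeasible"} when the constraints cannot be met
#' at all -- in the photo-electro-autotrophic scenarios this happens when
#' the PPR bound cannot cover the ATP maintenance demand.
#'
#' @param sm a \code{scenario_model} (or bare \code{metabolic_model} with a
#'   biomass reaction).
#' @return object of class \code{flux_solution}: list with
#'   \code{growth_rate} (h^-1), \code{fluxes} (named, mmol/gCDW/h) and
#'   \code{status}.
#' @export
#' @examples
#' sm <- build_scenario(load_core_model(),
#'                      scenario_config("rtca", ngam = 1, ppr_upper_bound = 50))
#' maximize_growth(sm)$growth_rate
maximize_growth <- function(sm) {
  model <- as_model(sm)
  if (is.null(model$biomass_id)) stop("model has no biomass reaction")
  lp <- lp_from_model(model, model$biomass_id)
  sol <- solve_lp(lp$obj, lp$A, lp$b, lp$lb, lp$ub, maximize = TRUE)
  fluxes <- sol$x
  names(fluxes) <- model$rxns$id
  structure(list(growth_rate = if (sol$status == "optimal") sol$objective else NA_real_,
                 fluxes = fluxes, status = sol$status),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> status: ", x$status,
      ", growth rate: ", format(x$growth_rate, digits = 4), " h^-1\n",
      sep = "")
  invisible(x)
}

#' Flux variability analysis at fixed growth
#'
#' Minimizes and maximizes each requested flux with the biomass flux pinned
#' to \code{fixed_growth}, probing degeneracy of the optimum.
#'
#' @param sm a \code{scenario_model} or \code{metabolic_model}.
#' @param fixed_growth growth rate to pin (default: the FBA optimum).
#' @param reactions reaction ids to analyze (default all).
#' @param tol numeric slack applied to the growth pin.
#' @return data.frame with \code{id}, \code{min_flux}, \code{max_flux},
#'   and \code{variable} (range wider than 1e-6).
#' @export
flux_variability <- function(sm, fixed_growth = NULL, reactions = NULL,
                             tol = 1e-9) {
  model <- as_model(sm)
  if (is.null(fixed_growth)) {
    opt <- maximize_growth(sm)
    if (opt$status != "optimal") stop("cannot pin growth: model infeasible")
    fixed_growth <- opt$growth_rate
  }
  model <- set_bounds(model, model$biomass_id,
                      lb = fixed_growth - tol, ub = fixed_growth + tol)
  if (is.null(reactions)) reactions <- model$rxns$id
  res <- data.frame(id = reactions, min_flux = NA_real_, max_flux = NA_real_)
  for (k in seq_along(reactions)) {
    lp <- lp_from_model(model, reactions[k])
    lo <- solve_lp(lp$obj, lp$A, lp$b, lp$lb, lp$ub, maximize = FALSE)
    hi <- solve_lp(lp$obj, lp$A, lp$b, lp$lb, lp$ub, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("growth pin infeasible at ", fixed_growth)
    res$min_flux[k] <- lo$objective
    res$max_flux[k] <- hi$objective
  }
  res$variable <- (res$max_flux - res$min_flux) > 1e-6
  res
}

#' Sweep the PPR proton-pumping bound
#'
#' Re-solves the growth maximization for every grid point of the PPR upper
#' bound. Infeasible points (maintenance not covered) are recorded with
#' growth 0 and \code{feasible = FALSE}; the threshold is the smallest grid
#' point at which the model is feasible.
#'
#' @param base base \code{metabolic_model}.
#' @param scenario a [scenario_config()]; its \code{ppr_upper_bound} is
#'   replaced by each grid value in turn.
#' @param grid ascending PPR bounds (mmol H+/gCDW/h); default 0 to 50 in
#'   0.5 steps.
#' @return object of class \code{sweep_result}: data.frame with
#'   \code{ppr_bound}, \code{growth}, \code{feasible}; attribute
#'   \code{threshold}.
#' @export
sweep_ppr <- function(base, scenario, grid = seq(0, 50, by = 0.5)) {
  if (length(grid) == 0L) stop("empty PPR grid")
  if (is.unsorted(grid)) stop("PPR grid must be sorted ascending")
  sm <- build_scenario(base, scenario)
  growth <- numeric(length(grid))
  feasible <- logical(length(grid))
  for (k in seq_along(grid)) {
    sm$model <- set_bounds(sm$model, "PPR", lb = 0, ub = grid[k])
    sol <- maximize_growth(sm)
    feasible[k] <- sol$status == "optimal"
    growth[k] <- if (feasible[k]) sol$growth_rate else 0
  }
  out <- data.frame(ppr_bound = grid, growth = growth, feasible = feasible)
  attr(out, "threshold") <- if (any(feasible)) grid[which(feasible)[1]] else NA_real_
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Uptake fluxes of an optimal solution
#'
#' @param sol a \code{flux_solution} with status \code{"optimal"}.
#' @return list with \code{electron_uptake}, \code{co2_uptake} (both as
#'   positive uptake rates, mmol/gCDW/h) and \code{ppr_flux}.
#' @export
uptake_summary <- function(sol) {
  if (!inherits(sol, "flux_solution") || sol$status != "optimal")
    stop("uptake_summary() needs an optimal flux solution")
  list(electron_uptake = -unname(sol$fluxes["EX_ee"]),
       co2_uptake = -unname(sol$fluxes["EX_co2_e"]),
       ppr_flux = unname(sol$fluxes["PPR"]))
}

#' Membrane proton budget of an optimal solution
#'
#' Decomposes the production of extracellular protons across the membrane:
#' the PPR pump, the proton-translocating NADH dehydrogenase that recovers
#' ubiquinol formed by fumarate reduction, the ATP synthase influx, the
#' medium proton exchange, and everything else (proton-coupled
#' transporters). Because extracellular protons are mass-balanced, the
#' components sum to zero.
#'
#' @param sol optimal \code{flux_solution}.
#' @param sm the \code{scenario_model} it came from.
#' @return list with \code{ppr_efflux}, \code{quinol_linked_efflux},
#'   \code{atp_synthase_influx}, \code{medium_proton_exchange},
#'   \code{other}, and \code{net} (conservation check, ~0).
#' @export
proton_balance <- function(sol, sm) {
  if (!inherits(sol, "flux_solution") || sol$status != "optimal")
    stop("proton_balance() needs an optimal flux solution")
  model <- as_model(sm)
  if (!"h_e" %in% rownames(model$S)) stop("model has no extracellular proton")
  prod <- model$S["h_e", ] * sol$fluxes  # production rate of h_e per reaction
  get <- function(id) if (id %in% names(prod)) unname(prod[id]) else 0
  ppr <- get("PPR")
  nadh16 <- get("NADH16")
  atps <- -get("ATPS4r")          # influx: protons consumed by the synthase
  exch <- get("EX_h_e")           # exchange production (negative = secreted)
  other <- sum(prod) - ppr - nadh16 - (-atps) - exch
  list(ppr_efflux = ppr,
       quinol_linked_efflux = nadh16,
       atp_synthase_influx = atps,
       medium_proton_exchange = exch,
       other = other,
       net = sum(prod))
}

#' Steady-state mass balance residual
#' @param sm scenario or metabolic model.
#' @param sol flux solution.
#' @return maximum absolute element of \eqn{S v}.
#' @export
mass_balance_residual <- function(sm, sol) {
  model <- as_model(sm)
  max(abs(model$S %*% sol$fluxes))
}
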