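## Max-min Driving Force analysis: maximize the smallest thermodynamic
## driving force -drG' over metabolite log-concentrations, as a linear
## program in ln(c) space.

#' Thermodynamic settings
#'
#' @param temperature Kelvin. The default 298.15 K is used for all
#'   thermodynamic arithmetic including the flux-force efficacy; 310.15 K
#'   remains selectable.
#' @param ph,ionic_strength condition of the transformed energies.
#' @return list with \code{R} (8.314 J/mol/K), \code{temperature},
#'   \code{RT} (kJ/mol), \code{ph}, \code{ionic_strength}.
#' @export
thermo_settings <- function(temperature = 298.15, ph = 7.5,
                            ionic_strength = 0.2) {
  if (!is.numeric(temperature) || temperature <= 0)
    stop("temperature must be positive (Kelvin)")
  list(R = 8.314, temperature = temperature,
       RT = 8.314e-3 * temperature, ph = ph,
       ionic_strength = ionic_strength)
}

#' Concentration constraints for the MDF program
#'
#' Three kinds are supported: \code{fixed} pins a concentration,
#' \code{range} bounds it, and \code{ratio} ties two metabolites by an
#' exact ratio in log space while leaving both otherwise free.
#'
#' @param metabolite metabolite name (thermo-table dialect, e.g.
#'   \code{"atp"}).
#' @param value,lo,hi concentrations in M.
#' @param partner,ratio for \code{conc_ratio}: \code{metabolite} =
#'   \code{ratio} * \code{partner}.
#' @return one-row data.frame; bind rows to form a constraint set.
#' @export
conc_fixed <- function(metabolite, value) {
  stopifnot(value > 0)
  data.frame(metabolite = metabolite, kind = "fixed", lo = value, hi = value,
             partner = NA_character_, ratio = NA_real_,
             stringsAsFactors = FALSE)
}

#' @rdname conc_fixed
#' @export
conc_range <- function(metabolite, lo, hi) {
  stopifnot(lo > 0, lo <= hi)
  data.frame(metabolite = metabolite, kind = "range", lo = lo, hi = hi,
             partner = NA_character_, ratio = NA_real_,
             stringsAsFactors = FALSE)
}

#' @rdname conc_fixed
#' @export
conc_ratio <- function(metabolite, partner, ratio) {
  stopifnot(ratio > 0)
  data.frame(metabolite = metabolite, kind = "ratio", lo = NA_real_,
             hi = NA_real_, partner = partner, ratio = ratio,
             stringsAsFactors = FALSE)
}

#' Physiological concentration constraints of the standard condition
#'
#' Fixed: CO2 (aq) 0.3 mM, HCO3- 7 mM, orthophosphate 10 mM, pyrophosphate
#' 1 mM, CoA 1 mM. Ratios: ATP/ADP 10, ADP/AMP 1, NADPH/NADP+ 10,
#' NADH/NAD+ 0.1, ferredoxin(red)/ferredoxin(ox) 10. Everything else
#' ranges over 1 uM - 10 mM.
#'
#' @param co2,hco3 override the fixed inorganic carbon concentrations (M).
#' @param atp_adp,adp_amp,nadph_nadp,nadh_nad,fd_ratio override ratios.
#' @return constraint data.frame.
#' @export
default_concentrations <- function(co2 = 3e-4, hco3 = 7e-3, atp_adp = 10,
                                   adp_amp = 1, nadph_nadp = 10,
                                   nadh_nad = 0.1, fd_ratio = 10) {
  rbind(
    conc_fixed("co2", co2),
    conc_fixed("hco3", hco3),
    conc_fixed("pi", 1e-2),
    conc_fixed("ppi", 1e-3),
    conc_fixed("coa", 1e-3),
    conc_ratio("atp", "adp", atp_adp),
    conc_ratio("adp", "amp", adp_amp),
    conc_ratio("nadph", "nadp", nadph_nadp),
    conc_ratio("nadh", "nad", nadh_nad),
    conc_ratio("fdrd", "fdox", fd_ratio)
  )
}

#' Max-min Driving Force of a pathway
#'
#' Maximizes B subject to
#' \eqn{-\Delta_r G'^0_r - \delta_r - RT \sum_j s_{rj} \ln c_j \ge B}
#' for every reaction, with concentration, ratio and (optionally)
#' energy-uncertainty constraints \eqn{|\delta_r| \le se_r}. A pathway is
#' thermodynamically feasible when the optimum B is positive. Water and
#' protons are inside the transformed energies and never appear as
#' concentration variables.
#'
#' @param thermo data.frame with \code{reaction_id}, \code{equation},
#'   \code{drg0_prime} (kJ/mol) and, if \code{use_uncertainty}, \code{se};
#'   e.g. from [thermo_table()].
#' @param constraints constraint data.frame (default
#'   [default_concentrations()]).
#' @param settings a [thermo_settings()].
#' @param use_uncertainty allow each reaction energy to shift by at most
#'   one standard error, as in the updated MDF formulation that
#'   incorporates the uncertainty of the energy estimates.
#' @param conc_range default concentration range (M) for unconstrained
#'   metabolites.
#' @param stoich optional reaction x metabolite stoichiometric matrix
#'   overriding the equations (reactions are taken exactly as written;
#'   no normalization is applied).
#' @return object of class \code{mdf_result}: list with \code{mdf}
#'   (kJ/mol), \code{ln_concentrations}, \code{driving_forces},
#'   \code{bottlenecks} (reactions within 1e-6 kJ/mol of the minimum),
#'   \code{shifts} (the applied energy shifts), \code{status}.
#' @export
#' @examples
#' th <- data.frame(reaction_id = "R1", equation = "1 a -> 1 b",
#'                  drg0_prime = 0, se = 0)
#' mdf(th, constraints = NULL)$mdf  # RT ln(1e4) = 22.8 kJ/mol
mdf <- function(thermo, constraints = default_concentrations(),
                settings = thermo_settings(), use_uncertainty = FALSE,
                conc_range = c(1e-6, 1e-2), stoich = NULL) {
  RT <- settings$RT
  nr <- nrow(thermo)
  if (nr == 0L) stop("no reactions in thermo table")
  if (is.null(stoich)) {
    st <- lapply(thermo$equation, function(e) parse_equation(e)$stoich)
    mets <- sort(unique(unlist(lapply(st, names))))
    stoich <- matrix(0, nr, length(mets),
                     dimnames = list(thermo$reaction_id, mets))
    for (r in seq_len(nr)) stoich[r, names(st[[r]])] <- st[[r]]
  } else {
    stoich <- as.matrix(stoich)
    mets <- colnames(stoich)
  }
  nm <- length(mets)
  if (is.null(constraints))
    constraints <- data.frame(metabolite = character(0), kind = character(0),
                              lo = numeric(0), hi = numeric(0),
                              partner = character(0), ratio = numeric(0))
  constraints <- constraints[constraints$metabolite %in% mets |
                               (!is.na(constraints$partner) &
                                  constraints$partner %in% mets), ,
                             drop = FALSE]

  use_se <- isTRUE(use_uncertainty)
  se <- if (use_se) {
    if (!"se" %in% names(thermo)) stop("use_uncertainty needs an 'se' column")
    if (any(thermo$se < 0)) stop("standard errors must be nonnegative")
    thermo$se
  } else rep(0, nr)

  ## variables: ln c (nm), B, slack per reaction (nr), delta per reaction
  nv <- nm + 1L + nr + (if (use_se) nr else 0L)
  iB <- nm + 1L
  islack <- nm + 1L + seq_len(nr)
  idelta <- if (use_se) nm + 1L + nr + seq_len(nr) else integer(0)

  lb <- c(rep(log(conc_range[1]), nm), -1e4, rep(0, nr),
          if (use_se) -se)
  ub <- c(rep(log(conc_range[2]), nm), 1e4, rep(1e5, nr),
          if (use_se) se)
  for (i in seq_len(nrow(constraints))) {
    cs <- constraints[i, ]
    if (cs$kind %in% c("fixed", "range") && cs$metabolite %in% mets) {
      j <- match(cs$metabolite, mets)
      lb[j] <- log(cs$lo); ub[j] <- log(cs$hi)
    }
  }
  ratios <- constraints[constraints$kind == "ratio", , drop = FALSE]
  ratios <- ratios[ratios$metabolite %in% mets & ratios$partner %in% mets, ,
                   drop = FALSE]

  ## equalities: per reaction  RT * s_r . lnc + B + slack_r + delta_r = -dG0_r
  ## plus ratio rows  ln c_a - ln c_b = ln ratio
  neq <- nr + nrow(ratios)
  A <- matrix(0, neq, nv)
  b <- numeric(neq)
  for (r in seq_len(nr)) {
    A[r, seq_len(nm)] <- RT * stoich[r, ]
    A[r, iB] <- 1
    A[r, islack[r]] <- 1
    if (use_se) A[r, idelta[r]] <- 1
    b[r] <- -thermo$drg0_prime[r]
  }
  if (nrow(ratios) > 0L) {
    for (i in seq_len(nrow(ratios))) {
      r <- nr + i
      A[r, match(ratios$metabolite[i], mets)] <- 1
      A[r, match(ratios$partner[i], mets)] <- -1
      b[r] <- log(ratios$ratio[i])
    }
  }
  obj <- numeric(nv); obj[iB] <- 1
  sol <- solve_lp(obj, A, b, lb, ub, maximize = TRUE)
  if (sol$status != "optimal") {
    bad <- constraints[constraints$kind != "range", , drop = FALSE]
    stop("MDF constraint system infeasible; check fixed/ratio constraints on: ",
         paste(unique(stats::na.omit(c(bad$metabolite, bad$partner))),
               collapse = ", "))
  }
  lnc <- stats::setNames(sol$x[seq_len(nm)], mets)
  shifts <- if (use_se) stats::setNames(sol$x[idelta], thermo$reaction_id)
            else stats::setNames(rep(0, nr), thermo$reaction_id)
  df <- -(thermo$drg0_prime + shifts) -
    RT * as.numeric(stoich %*% lnc)
  names(df) <- thermo$reaction_id
  B <- sol$objective
  structure(list(mdf = B,
                 ln_concentrations = lnc,
                 driving_forces = df,
                 bottlenecks = thermo$reaction_id[df < B + 1e-6],
                 shifts = shifts,
                 status = "optimal"),
            class = "mdf_result")
}

#' @export
print.mdf_result <- function(x, ...) {
  cat("<mdf_result> MDF = ", format(x$mdf, digits = 4),
      " kJ/mol; bottleneck(s): ",
      paste(x$bottlenecks, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Default sensitivity grids for [mdf_sensitivity()]
#' @keywords internal
sensitivity_grids <- function() {
  list(fd_ratio = c(0.5, 1, 5, 10, 20, 50),
       atp_adp = c(5, 10, 15, 20),
       nadph_nadp = c(0.5, 1, 5, 10, 20, 50),
       nadh_nad = c(0.1, 0.5, 1, 5, 10),
       co2 = c(1e-5, 3e-5, 1e-4, 3e-4, 1e-3, 3e-3),
       hco3 = c(2.5e-4, 1e-3, 7e-3, 2e-2, 7e-2),
       ph = seq(5, 9, by = 0.5))
}

#' MDF sensitivity sweep over one condition parameter
#'
#' Re-optimizes the MDF while varying one cofactor ratio, one inorganic
#' carbon concentration, or the pH, everything else held at the standard
#' condition.
#'
#' @param pathway pathway token.
#' @param vary one of \code{"fd_ratio"}, \code{"atp_adp"},
#'   \code{"nadph_nadp"}, \code{"nadh_nad"}, \code{"co2"}, \code{"hco3"},
#'   \code{"ph"}.
#' @param grid values to sweep (defaults to the standard analysis ranges).
#' @param settings a [thermo_settings()].
#' @param use_uncertainty see [mdf()].
#' @param ... passed to [thermo_table()] (e.g. \code{gapd_nadph}).
#' @return data.frame with \code{value}, \code{mdf}, \code{bottlenecks}
#'   (collapsed labels).
#' @export
mdf_sensitivity <- function(pathway, vary, grid = NULL,
                            settings = thermo_settings(),
                            use_uncertainty = FALSE, ...) {
  valid <- names(sensitivity_grids())
  if (!vary %in% valid)
    stop("unknown sensitivity parameter '", vary, "'; expected one of: ",
         paste(valid, collapse = ", "))
  if (is.null(grid)) grid <- sensitivity_grids()[[vary]]
  out <- data.frame(value = grid, mdf = NA_real_,
                    bottlenecks = NA_character_)
  for (k in seq_along(grid)) {
    v <- grid[k]
    th <- thermo_table(pathway, ph = if (vary == "ph") v else 7.5, ...)
    cons <- switch(vary,
      fd_ratio = default_concentrations(fd_ratio = v),
      atp_adp = default_concentrations(atp_adp = v),
      nadph_nadp = default_concentrations(nadph_nadp = v),
      nadh_nad = default_concentrations(nadh_nad = v),
      co2 = default_concentrations(co2 = v),
      hco3 = default_concentrations(hco3 = v),
      ph = default_concentrations())
    res <- mdf(th, constraints = cons, settings = settings,
               use_uncertainty = use_uncertainty)
    out$mdf[k] <- res$mdf
    out$bottlenecks[k] <- paste(res$bottlenecks, collapse = ";")
  }
  out
}
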