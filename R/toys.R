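## Synthetic fixtures with analytically known answers, so that the LP
## engine, the MDF program and the aggregation rule can be tested without
## any external input. Generation is restricted to structures whose optimum
## is known in closed form -- never "generate, then solve with the engine
## under test".

#' Toy energy-coupled FBA model with a planted growth optimum
#'
#' A minimal proton-pumped cell: a pump moves protons out (capped at
#' \code{ppr}), an ATP synthase makes one ATP per \code{k} protons
#' re-entering, maintenance consumes at least \code{ngam} ATP, and the
#' biomass reaction spends \code{a} ATP per unit growth. The optimum is
#' \eqn{(ppr/k - ngam)/a} when nonnegative, otherwise the model is
#' infeasible.
#'
#' @param ppr pump bound (mmol H+/gCDW/h).
#' @param ngam maintenance demand.
#' @param k protons translocated per ATP (default 4).
#' @param a ATP per unit biomass (default 10).
#' @return list with \code{model} (a \code{metabolic_model}) and
#'   \code{expected_growth} (\code{NA} when infeasible).
#' @export
#' @examples
#' make_toy_fba_model(ppr = 8, ngam = 1, k = 4, a = 10)$expected_growth
make_toy_fba_model <- function(ppr, ngam, k = 4, a = 10) {
  mets <- data.frame(id = c("h_c", "h_e", "atp_c", "adp_c"),
                     name = c("proton (cytoplasm)", "proton (medium)",
                              "ATP", "ADP"),
                     compartment = c("c", "e", "c", "c"),
                     formula = c("H", "H", "C10H12N5O13P3", "C10H12N5O10P2"),
                     stringsAsFactors = FALSE)
  rxns <- data.frame(
    id = c("PUMP", "ATPS", "ATPM", "BIO"),
    name = c("proton pump", "ATP synthase", "maintenance", "biomass"),
    lower = c(0, 0, ngam, 0),
    upper = c(ppr, 1000, 1000, 1000),
    equation = c("1 h_c -> 1 h_e",
                 sprintf("%.17g h_e + 1 adp_c -> 1 atp_c + %.17g h_c", k, k),
                 "1 atp_c -> 1 adp_c",
                 sprintf("%.17g atp_c -> %.17g adp_c", a, a)),
    stringsAsFactors = FALSE)
  model <- model_from_tables(mets, rxns, biomass_id = "BIO", ngam_id = "ATPM")
  expected <- (ppr / k - ngam) / a
  list(model = model,
       expected_growth = if (expected >= -1e-12) max(expected, 0) else NA_real_)
}

#' Toy two-branch network with a degenerate optimum
#'
#' A substrate is imported and converted to the objective product through
#' two parallel, equally-priced routes; the optimum is unique in value but
#' the branch fluxes are free to trade off, which flux variability must
#' report as nonzero-width ranges.
#'
#' @param supply import bound.
#' @return list with \code{model} and \code{expected_growth} (= supply).
#' @export
make_toy_branch_model <- function(supply = 5) {
  mets <- data.frame(id = c("a_e", "a_c", "b_c"),
                     name = c("A (medium)", "A", "B"),
                     compartment = c("e", "c", "c"),
                     formula = c("C", "C", "C"),
                     stringsAsFactors = FALSE)
  rxns <- data.frame(
    id = c("EX_a", "T1", "T2", "BIO"),
    name = c("A exchange", "branch 1", "branch 2", "sink"),
    lower = c(-supply, 0, 0, 0),
    upper = c(0, 1000, 1000, 1000),
    equation = c("1 a_e ->", "1 a_e -> 1 b_c", "1 a_e -> 1 b_c",
                 "1 b_c ->"),
    stringsAsFactors = FALSE)
  ## EX_a written as consumption of a_e with negative lower bound = import
  rxns$equation[1] <- "1 a_e <->"
  model <- model_from_tables(mets, rxns, biomass_id = "BIO")
  list(model = model, expected_growth = supply)
}

#' Toy linear thermodynamic chain with closed-form MDF
#'
#' A chain of n unimolecular reactions A0 -> A1 -> ... -> An with chosen
#' standard energies; the first substrate is fixed at the upper end of the
#' concentration range and the final product at the lower end, so the
#' optimal profile distributes the total drive
#' \eqn{RT\ln(hi/lo) + \sum_i(-\Delta G_i)} equally:
#' \eqn{B = (RT\ln(hi/lo) + \sum_i -\Delta G_i)/n}. Random energies are
#' drawn small enough that the equalizing profile stays inside the range,
#' which keeps the closed form exact.
#'
#' @param n_reactions chain length (>= 1).
#' @param seed integer seed for the random energies.
#' @param dg optional explicit vector of standard energies (kJ/mol).
#' @param conc_range concentration range (M) for the free intermediates.
#' @return list with \code{thermo}, \code{constraints},
#'   \code{expected_mdf}, and \code{settings}.
#' @export
#' @examples
#' make_toy_thermo_pathway(2, seed = 1, dg = c(0, 0))$expected_mdf  # 11.42
make_toy_thermo_pathway <- function(n_reactions, seed = 1L, dg = NULL,
                                    conc_range = c(1e-6, 1e-2)) {
  stopifnot(n_reactions >= 1L)
  if (is.null(dg)) {
    set.seed(seed)
    dg <- stats::runif(n_reactions, -5, 5)
  }
  stopifnot(length(dg) == n_reactions)
  mets <- paste0("m", 0:n_reactions)
  thermo <- data.frame(
    reaction_id = paste0("R", seq_len(n_reactions)),
    equation = paste0("1 ", mets[-length(mets)], " -> 1 ", mets[-1]),
    drg0_prime = dg,
    se = 0,
    stringsAsFactors = FALSE)
  constraints <- rbind(conc_fixed(mets[1], conc_range[2]),
                       conc_fixed(mets[length(mets)], conc_range[1]))
  RT <- 8.314e-3 * 298.15
  total <- RT * log(conc_range[2] / conc_range[1]) + sum(-dg)
  B <- total / n_reactions
  ## verify the equalizing profile is attainable within the range; callers
  ## passing extreme energies get NA and should regenerate
  lnc <- log(conc_range[2])
  ok <- TRUE
  for (i in seq_len(n_reactions)) {
    lnc <- lnc + (-dg[i] - B) / RT
    if (i < n_reactions &&
        (lnc < log(conc_range[1]) - 1e-9 || lnc > log(conc_range[2]) + 1e-9))
      ok <- FALSE
  }
  list(thermo = thermo, constraints = constraints,
       expected_mdf = if (ok) B else NA_real_,
       settings = thermo_settings())
}

#' Toy specific-activity collection with known trimmed mean
#'
#' Log-normal draws plus the hand-evaluated trim rule (sort, drop
#' floor(n/2) lowest and floor(n/10) highest, average the rest), computed
#' here independently of [aggregate_specific_activity()].
#'
#' @param n number of observations.
#' @param seed integer seed.
#' @return list with \code{values} and \code{expected_trimmed_mean}.
#' @export
make_toy_activities <- function(n, seed = 1L) {
  stopifnot(n >= 1L)
  set.seed(seed)
  values <- stats::rlnorm(n, meanlog = 1, sdlog = 1)
  v <- values[order(values)]
  keep <- v[(floor(n / 2) + 1):(n - floor(n / 10))]
  list(values = values, expected_trimmed_mean = sum(keep) / length(keep))
}
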