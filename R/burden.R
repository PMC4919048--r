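## Protein burden of the autotrophy systems: grams of pathway or
## single-system protein per gram cell dry weight needed to sustain a flux.

#' Protein burden of a flux-carrying system
#'
#' \eqn{PB = F / (n \cdot SA)} with the flux F in mmol/gCDW/h converted to
#' umol/gCDW/min, the specific activity SA in umol/mg protein/min, and n a
#' stoichiometric divisor (molecules of the measured substrate per molecule
#' of product; e.g. the number of inorganic carbons per pyruvate for a
#' fixation pathway, or electrons per formate for an uptake enzyme).
#'
#' @param flux F, mmol/gCDW/h (nonnegative).
#' @param n stoichiometric divisor (>= 1).
#' @param activity specific activity (umol/mg protein/min) -- a PSA for a
#'   pathway, an SA for a single system.
#' @param proteome_per_cdw proteome mass fraction of cell dry weight used
#'   for the proteome-share conversion (default 0.5).
#' @return list with \code{burden} (g protein/gCDW), \code{percent_cdw}
#'   and \code{proteome_fraction}.
#' @export
#' @examples
#' protein_burden(50, n = 1, activity = 10.3)$percent_cdw  # ~8.1 %
protein_burden <- function(flux, n = 1, activity, proteome_per_cdw = 0.5) {
  if (!is.numeric(flux) || flux < 0) stop("flux must be >= 0")
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  if (!is.numeric(activity) || activity <= 0)
    stop("specific activity must be positive")
  mg_per_g <- (flux * 1000 / 60) / (n * activity)
  burden <- mg_per_g / 1000
  list(burden = burden,
       percent_cdw = 100 * burden,
       proteome_fraction = burden / proteome_per_cdw)
}

#' Specific activity from a molar turnover rate
#'
#' @param turnover mmol substrate/mmol protein/min.
#' @param mw protein molecular weight in kDa.
#' @return umol substrate/mg protein/min.
#' @export
#' @examples
#' specific_activity_from_turnover(300, 29)  # proteorhodopsin, ~10.3
specific_activity_from_turnover <- function(turnover, mw) {
  if (!is.numeric(turnover) || turnover <= 0) stop("turnover must be positive")
  if (!is.numeric(mw) || mw <= 0) stop("molecular weight must be positive")
  turnover / mw
}

#' Protein molecules per cell required for a flux
#'
#' @param flux mmol/gCDW/h.
#' @param turnover molecules of substrate per protein per minute.
#' @param cell_mass gCDW per cell (default 3e-13).
#' @return expected number of protein molecules per cell.
#' @export
#' @examples
#' molecules_per_cell(50, 300)  # ~5e5 proton pumps
molecules_per_cell <- function(flux, turnover, cell_mass = 3e-13) {
  if (any(c(flux, turnover, cell_mass) < 0)) stop("inputs must be nonnegative")
  avogadro <- 6.02214076e23
  flux * 1e-3 * cell_mass * avogadro / 60 / turnover
}
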