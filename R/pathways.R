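## Pathway library: the six carbon fixation pathways, the proton-pumping
## rhodopsin (PPR) reaction and the electron-uptake module, with their
## thermodynamic and kinetic annotations, all backed by plain-text fixtures
## under inst/extdata.

the <- new.env(parent = emptyenv())

read_fixture <- function(file) {
  key <- paste0("fx_", file)
  if (!is.null(the[[key]])) return(the[[key]])
  path <- system.file("extdata", file, package = "carbfix", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                          na.strings = character(0))
  the[[key]] <- df
  df
}

split_tokens <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0)
  else strsplit(x, ";", fixed = TRUE)[[1]]
}

#' Names of the available carbon fixation pathways
#' @return character vector of the six pathway tokens.
#' @export
pathway_names <- function() read_fixture("pathway_meta.tsv")$name

check_pathway_name <- function(name) {
  valid <- pathway_names()
  if (!is.character(name) || length(name) != 1L || !name %in% valid)
    stop("unknown pathway '", name, "'; valid tokens: ",
         paste(valid, collapse = ", "))
  name
}

#' Retrieve a carbon fixation pathway definition
#'
#' Returns the reaction set of one pathway as reconstructed from the
#' published cycle descriptions: the cycle enzymes proper, plus any
#' assimilation or helper steps (pyruvate synthase where the cycle product
#' is acetyl-CoA, carbonic anhydrase, pyrophosphatase). Reactions are
#' oriented toward net carbon fixation; ferredoxin-coupled steps consume
#' reduced ferredoxin. Each reaction row records whether it is already
#' native to the core network (\code{action == "reuse"}), must be added
#' (\code{"add"}), or needs its bounds opened (\code{"widen"}, the
#' isocitrate lyase of the glyoxylate-assimilating bicycles), and how many
#' ATP equivalents it spends (2 for AMP-forming synthetases).
#'
#' @param name one of [pathway_names()].
#' @return object of class \code{pathway_definition}: a list with
#'   \code{name}, \code{label}, \code{reactions} (data.frame),
#'   \code{enzyme_count}, \code{electron_donors}, \code{carbon_species},
#'   \code{knockouts}, \code{end_product}, \code{n_carbons_per_product}.
#' @export
#' @examples
#' get_pathway("rtca")$enzyme_count
get_pathway <- function(name) {
  check_pathway_name(name)
  meta <- read_fixture("pathway_meta.tsv")
  meta <- meta[meta$name == name, ]
  rx <- read_fixture("pathway_reactions.tsv")
  in_pw <- vapply(rx$pathways, function(p) name %in% split_tokens(p),
                  logical(1))
  rx <- rx[in_pw, , drop = FALSE]
  rx$in_cycle <- !vapply(rx$noncycle_in,
                         function(p) name %in% split_tokens(p), logical(1))
  rx$noncycle_in <- NULL
  rownames(rx) <- NULL
  structure(list(
    name = name,
    label = meta$label,
    reactions = rx,
    enzyme_count = meta$enzyme_count,
    electron_donors = split_tokens(meta$electron_donors),
    carbon_species = split_tokens(meta$carbon_species),
    knockouts = split_tokens(meta$knockouts),
    end_product = meta$end_product,
    n_carbons_per_product = meta$n_carbons_per_product
  ), class = "pathway_definition")
}

#' @export
print.pathway_definition <- function(x, ...) {
  cat("<pathway_definition> ", x$label, " ('", x$name, "')\n", sep = "")
  cat("  ", x$enzyme_count, " cycle enzymes, ", nrow(x$reactions),
      " reactions; donors: ", paste(x$electron_donors, collapse = ", "),
      "; carbon: ", paste(x$carbon_species, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' The PPR photosystem and electron-uptake reactions
#'
#' The energy module shared by every scenario: the proton-pumping rhodopsin
#' modeled as a cytoplasm-to-medium proton translocation (the core network
#' has no periplasm), an exchange for extracellular electrons, and the two
#' regeneration reactions that convert those electrons into NADPH (2 e- and
#' one cytoplasmic proton per NADPH) and reduced ferredoxin (1 e- each).
#' No NADH regeneration reaction exists; NADH is supplied from NADPH via
#' the native transhydrogenase.
#'
#' @return data.frame of reactions in the pathway fixture layout.
#' @export
energy_module_reactions <- function() {
  rx <- read_fixture("pathway_reactions.tsv")
  rx <- rx[vapply(rx$pathways, function(p) "energy" %in% split_tokens(p),
                  logical(1)), , drop = FALSE]
  rx$noncycle_in <- NULL
  rownames(rx) <- NULL
  rx
}

#' Standard transformed Gibbs energies for a pathway
#'
#' Returns one annotation per pathway reaction at the requested pH (ionic
#' strength fixed at 0.2 M). The packaged table holds reconstructed
#' (synthetic) estimates at pH 7.5; other pH values on the supported grid
#' are derived by the first-order adjustment
#' \eqn{\Delta_r G'^0(pH) = \Delta_r G'^0(7.5) + \nu_H RT \ln 10 (pH - 7.5)}
#' using the per-reaction net transformed proton production \eqn{\nu_H}.
#'
#' @param name pathway token.
#' @param ph pH on the grid 5.0, 5.5, ..., 9.0.
#' @param gapd_nadph for the Calvin cycle, use the NADPH-dependent
#'   glyceraldehyde-3-phosphate dehydrogenase variant instead of the native
#'   NADH-dependent one.
#' @return data.frame with columns \code{reaction_id}, \code{enzyme},
#'   \code{equation}, \code{drg0_prime}, \code{se}, \code{ph},
#'   \code{ionic_strength}.
#' @export
#' @examples
#' head(thermo_table("rtca"))
thermo_table <- function(name, ph = 7.5, gapd_nadph = FALSE) {
  check_pathway_name(name)
  grid <- seq(5, 9, by = 0.5)
  if (!isTRUE(any(abs(grid - ph) < 1e-9)))
    stop("no thermodynamic fixture for pH ", ph,
         " (supported grid: 5.0 to 9.0 in 0.5 steps)")
  th <- read_fixture("thermo_reactions_synthetic.tsv")
  th <- th[th$pathway == name, , drop = FALSE]
  if (isTRUE(gapd_nadph) && name == "calvin") {
    i <- th$reaction_id == "GAPD"
    th$equation[i] <- "1 13dpg + 1 nadph -> 1 g3p + 1 nadp + 1 pi"
  }
  RT <- 8.314e-3 * 298.15
  th$drg0_prime <- th$drg0_prime + th$dnh * RT * log(10) * (ph - 7.5)
  th$dnh <- NULL
  th$pathway <- NULL
  th$ph <- ph
  th$ionic_strength <- 0.2
  rownames(th) <- NULL
  th
}

#' Enzyme kinetic annotations for a pathway
#'
#' Stoichiometric coefficients per mole of pyruvate end product and specific
#' activities (umol/mg protein/min, saturation assumed for all substrates
#' including the inorganic carbon species). Enzymes with an observation
#' collection in the packaged fixture get their specific activity from
#' [aggregate_specific_activity()] applied to those observations.
#'
#' @param name pathway token.
#' @return data.frame with columns \code{reaction_id}, \code{enzyme},
#'   \code{w}, \code{specific_activity}, \code{n_observations}.
#' @export
kinetics_table <- function(name) {
  check_pathway_name(name)
  kin <- read_fixture("kinetics_synthetic.tsv")
  kin <- kin[kin$pathway == name, , drop = FALSE]
  kin$pathway <- NULL
  obs <- read_fixture("activity_observations_synthetic.tsv")
  kin$n_observations <- 0L
  for (i in seq_len(nrow(obs))) {
    j <- kin$reaction_id == obs$reaction_id[i]
    if (any(j)) {
      vals <- as.numeric(split_tokens(obs$values[i]))
      kin$specific_activity[j] <- aggregate_specific_activity(vals)
      kin$n_observations[j] <- length(vals)
    }
  }
  rownames(kin) <- NULL
  kin
}

#' Observation collections behind aggregated specific activities
#' @return data.frame with \code{reaction_id}, \code{enzyme} and a list
#'   column \code{values}.
#' @export
activity_observations <- function() {
  obs <- read_fixture("activity_observations_synthetic.tsv")
  obs$values <- lapply(obs$values, function(v) as.numeric(split_tokens(v)))
  obs
}
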