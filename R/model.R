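#' Construct a stoichiometric metabolic model
#'
#' The central container of the package: a list of metabolites, a list of
#' reactions with flux bounds (mmol/gCDW/h), the stoichiometric matrix, and
#' the identities of the biomass objective and the ATP maintenance (NGAM)
#' reaction. Two compartments are recognized, \code{"c"} (cytoplasm) and
#' \code{"e"} (extracellular); the core network deliberately has no
#' periplasm, so proton-translocating steps connect \code{h_c} and \code{h_e}
#' directly.
#'
#' @param mets data.frame with columns \code{id}, \code{name},
#'   \code{compartment} (\code{"c"} or \code{"e"}), \code{formula}.
#' @param rxns data.frame with columns \code{id}, \code{name}, \code{lb},
#'   \code{ub}.
#' @param S stoichiometric matrix, metabolites x reactions, with dimnames
#'   matching \code{mets$id} and \code{rxns$id}.
#' @param biomass_id id of the biomass reaction (growth objective, h^-1).
#' @param ngam_id id of the ATP maintenance reaction whose lower bound
#'   carries the non-growth-associated maintenance, or \code{NULL}.
#' @return object of class \code{metabolic_model}.
#' @export
metabolic_model <- function(mets, rxns, S, biomass_id = NULL, ngam_id = NULL) {
  mets <- as.data.frame(mets, stringsAsFactors = FALSE)
  rxns <- as.data.frame(rxns, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "compartment") %in% names(mets)),
            all(c("id", "lb", "ub") %in% names(rxns)))
  if (!"name" %in% names(mets)) mets$name <- mets$id
  if (!"name" %in% names(rxns)) rxns$name <- rxns$id
  if (!"formula" %in% names(mets)) mets$formula <- ""
  if (anyDuplicated(mets$id)) stop("duplicated metabolite ids")
  if (anyDuplicated(rxns$id)) stop("duplicated reaction ids")
  bad <- !mets$compartment %in% c("c", "e")
  if (any(bad))
    stop("unrecognized compartment '", mets$compartment[bad][1],
         "' (expected 'c' or 'e')")
  S <- as.matrix(S)
  if (!identical(dim(S), c(nrow(mets), nrow(rxns))))
    stop("S has dimensions ", nrow(S), "x", ncol(S), ", expected ",
         nrow(mets), "x", nrow(rxns))
  dimnames(S) <- list(mets$id, rxns$id)
  if (any(rxns$lb > rxns$ub))
    stop("reaction ", rxns$id[which(rxns$lb > rxns$ub)[1]],
         " has lower bound above upper bound")
  if (any(colSums(abs(S)) == 0))
    stop("reaction ", rxns$id[which(colSums(abs(S)) == 0)[1]],
         " has empty stoichiometry")
  if (!is.null(biomass_id) && !biomass_id %in% rxns$id)
    stop("biomass reaction '", biomass_id, "' not in model")
  if (!is.null(ngam_id) && !ngam_id %in% rxns$id)
    stop("NGAM reaction '", ngam_id, "' not in model")
  mets$carbon <- count_carbon(mets$formula)
  structure(list(mets = mets, rxns = rxns, S = S,
                 biomass_id = biomass_id, ngam_id = ngam_id),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", nrow(x$rxns), " reactions, ",
      nrow(x$mets), " metabolites\n", sep = "")
  if (!is.null(x$biomass_id)) cat("  biomass: ", x$biomass_id, "\n", sep = "")
  if (!is.null(x$ngam_id))
    cat("  NGAM:    ", x$ngam_id, " (lb = ",
        x$rxns$lb[x$rxns$id == x$ngam_id], ")\n", sep = "")
  invisible(x)
}

#' Build a model from metabolite and reaction tables
#'
#' @param met_df metabolite table (\code{id}, \code{name}, \code{compartment},
#'   \code{formula}).
#' @param rxn_df reaction table with an \code{equation} column in the
#'   \code{"1 a + 2 b <-> 1 c"} dialect plus \code{lower}/\code{upper} bounds.
#' @param biomass_id,ngam_id reaction ids, see [metabolic_model()].
#' @return a \code{metabolic_model}.
#' @export
model_from_tables <- function(met_df, rxn_df, biomass_id = NULL,
                              ngam_id = NULL) {
  parsed <- lapply(rxn_df$equation, parse_equation)
  used <- unique(unlist(lapply(parsed, function(p) names(p$stoich))))
  missing <- setdiff(used, met_df$id)
  if (length(missing) > 0L)
    stop("equation references undeclared metabolite(s): ",
         paste(missing, collapse = ", "))
  S <- matrix(0, nrow(met_df), nrow(rxn_df),
              dimnames = list(met_df$id, rxn_df$id))
  for (j in seq_along(parsed))
    S[names(parsed[[j]]$stoich), j] <- parsed[[j]]$stoich
  rxns <- data.frame(id = rxn_df$id,
                     name = if ("name" %in% names(rxn_df)) rxn_df$name else rxn_df$id,
                     lb = as.numeric(rxn_df$lower),
                     ub = as.numeric(rxn_df$upper),
                     stringsAsFactors = FALSE)
  metabolic_model(met_df, rxns, S, biomass_id, ngam_id)
}

#' Load the packaged E. coli core network
#'
#' Reads the bundled plain-text copy of the published core metabolic network
#' of \emph{E. coli} (95 reactions, 72 metabolites, biomass objective with a
#' growth-associated maintenance of 59.81 mmol ATP/gCDW) from
#' \code{inst/extdata}.
#'
#' @return a \code{metabolic_model} with biomass and NGAM reactions set.
#' @export
#' @examples
#' m <- load_core_model()
#' m
load_core_model <- function() {
  metf <- system.file("extdata", "e_coli_core_metabolites.tsv",
                      package = "carbfix", mustWork = TRUE)
  rxnf <- system.file("extdata", "e_coli_core_reactions.tsv",
                      package = "carbfix", mustWork = TRUE)
  mets <- utils::read.delim(metf, stringsAsFactors = FALSE,
                            na.strings = character(0))
  rxns <- utils::read.delim(rxnf, stringsAsFactors = FALSE,
                            na.strings = character(0))
  model_from_tables(mets, rxns,
                    biomass_id = "Biomass_Ecoli_core", ngam_id = "ATPM")
}

#' Read a metabolic model from file
#'
#' Dispatches on the file extension: \code{.xml}/\code{.sbml} are parsed as
#' SBML (level 2 with COBRA kinetic-law bounds, or level 3 with fbc bounds).
#' The packaged core network is available through [load_core_model()].
#'
#' @param path file path.
#' @param ... passed to [read_sbml()].
#' @return a \code{metabolic_model}.
#' @export
read_model <- function(path, ...) {
  if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
    read_sbml(path, ...)
  else
    stop("unsupported model format: ", path,
         " (expected .xml/.sbml; use load_core_model() for the packaged network)")
}

## -- small accessors -------------------------------------------------------

n_reactions <- function(model) nrow(model$rxns)
n_metabolites <- function(model) nrow(model$mets)

#' Identify exchange reactions
#'
#' An exchange touches exactly one metabolite (flux into/out of the medium).
#' @param model a \code{metabolic_model}.
#' @return character vector of reaction ids.
#' @export
exchange_reactions <- function(model) {
  model$rxns$id[colSums(model$S != 0) == 1L]
}

#' Set flux bounds on one reaction
#' @param model a \code{metabolic_model}.
#' @param id reaction id.
#' @param lb,ub new bounds; \code{NULL} leaves a bound unchanged.
#' @return the modified model.
#' @export
set_bounds <- function(model, id, lb = NULL, ub = NULL) {
  i <- match(id, model$rxns$id)
  if (is.na(i)) stop("no reaction '", id, "' in model")
  if (!is.null(lb)) model$rxns$lb[i] <- lb
  if (!is.null(ub)) model$rxns$ub[i] <- ub
  if (model$rxns$lb[i] > model$rxns$ub[i])
    stop("bounds out of order for ", id)
  model
}

#' Set the non-growth-associated maintenance
#'
#' The NGAM is carried by the lower bound of the ATP maintenance reaction:
#' any feasible flux distribution must hydrolyse at least \code{ngam}
#' mmol ATP/gCDW/h. The published scenarios use 8.39 (standard aerobic
#' estimate) and 1.00 (low estimate for anaerobic electro-autotrophs).
#'
#' @param model a \code{metabolic_model} with \code{ngam_id} set.
#' @param ngam nonnegative maintenance flux (mmol ATP/gCDW/h).
#' @return the modified model.
#' @export
apply_ngam <- function(model, ngam) {
  if (!is.numeric(ngam) || length(ngam) != 1L || is.na(ngam) || ngam < 0)
    stop("ngam must be a single nonnegative number")
  if (is.null(model$ngam_id)) stop("model has no ATP maintenance reaction")
  set_bounds(model, model$ngam_id, lb = ngam)
}

#' Scenario configuration
#'
#' Bundles the knobs of one photo-electro-autotrophic scenario: which carbon
#' fixation pathway is engineered in, the maintenance demand, the upper bound
#' on the proton-pumping rhodopsin (PPR) flux, and whether secretion of
#' carbon by-products is blocked.
#'
#' @param pathway pathway token (see [pathway_names()]) or \code{"none"} for
#'   the bare energy module.
#' @param ngam non-growth-associated maintenance, mmol ATP/gCDW/h.
#' @param ppr_upper_bound PPR proton-pumping cap, mmol H+/gCDW/h (the
#'   published range is 0-50).
#' @param block_byproducts close every carbon exchange except CO2?
#' @param gam growth-associated maintenance, mmol ATP/gCDW; informational
#'   (the value lives inside the biomass reaction).
#' @return object of class \code{scenario_config}.
#' @export
#' @examples
#' scenario_config("rtca", ngam = 1.00, ppr_upper_bound = 50)
scenario_config <- function(pathway, ngam = 1.00, ppr_upper_bound = 50,
                            block_byproducts = TRUE, gam = 59.8) {
  stopifnot(is.character(pathway), length(pathway) == 1L)
  if (!is.numeric(ngam) || ngam < 0) stop("ngam must be >= 0")
  if (!is.numeric(ppr_upper_bound) || ppr_upper_bound < 0)
    stop("ppr_upper_bound must be >= 0")
  if (!is.numeric(gam) || gam <= 0) stop("gam must be > 0")
  structure(list(pathway_name = pathway, ngam = ngam,
                 ppr_upper_bound = ppr_upper_bound,
                 block_byproducts = isTRUE(block_byproducts), gam = gam),
            class = "scenario_config")
}

#' Write a keyed result table as TSV
#'
#' @param rows a data.frame, or a list of named lists sharing one key set.
#' @param path output path.
#' @param digits significant digits for numeric columns (default 3).
#' @return invisibly, the data.frame written.
#' @export
write_result_table <- function(rows, path, digits = 3) {
  if (is.data.frame(rows)) {
    df <- rows
  } else if (is.list(rows)) {
    if (length(rows) == 0L) {
      df <- data.frame()
    } else {
      keys <- names(rows[[1]])
      for (r in rows)
        if (!identical(sort(names(r)), sort(keys)))
          stop("records have mismatched keys: {",
               paste(names(r), collapse = ","), "} vs {",
               paste(keys, collapse = ","), "}")
      df <- do.call(rbind, lapply(rows, function(r)
        as.data.frame(r[keys], stringsAsFactors = FALSE)))
    }
  } else stop("rows must be a data.frame or list of records")
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]])) out[[j]] <- signif(out[[j]], digits)
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e)))
  on.exit(close(con))
  if (ncol(out) == 0L && !is.null(attr(rows, "keys")))
    writeLines(paste(attr(rows, "keys"), collapse = "\t"), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
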