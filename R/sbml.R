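## SBML import/export.
##
## The writer emits SBML Level 3 Version 1 with the fbc (version 2) flux
## bounds and objective, which is what current constraint-based toolboxes
## exchange. The reader additionally understands the older Level 2 "COBRA"
## dialect in which bounds travel as LOWER_BOUND/UPPER_BOUND kinetic-law
## parameters, and falls back to the conventional defaults (+-1000 for
## reversible reactions, [0, 1000] otherwise) when no bounds are present.
## Parsing is namespace-agnostic (local-name() XPath) so that files written
## by different tools resolve identically.

sbml_id <- function(id, prefix) {
  paste0(prefix, gsub("[^A-Za-z0-9_]", "_", id))
}

#' Write a model as SBML (Level 3 + fbc)
#'
#' @param model a \code{metabolic_model}.
#' @param path output file.
#' @param model_id id attribute for the SBML model element.
#' @return invisibly, \code{path}.
#' @export
write_sbml <- function(model, path, model_id = "model") {
  bounds <- sort(unique(c(model$rxns$lb, model$rxns$ub)))
  bnd_id <- function(v) paste0("bnd_", gsub("[^0-9A-Za-z]", "_", format(v)))
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  ln <- character(0)
  p <- function(...) ln[[length(ln) + 1L]] <<- paste0(...)
  p('<?xml version="1.0" encoding="UTF-8"?>')
  p('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
    'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
    'level="3" version="1" fbc:required="false">')
  p('  <model id="', model_id, '" fbc:strict="true">')
  p('    <listOfCompartments>')
  for (cid in unique(model$mets$compartment))
    p('      <compartment id="', cid, '" constant="true"/>')
  p('    </listOfCompartments>')
  p('    <listOfSpecies>')
  for (i in seq_len(nrow(model$mets))) {
    frm <- model$mets$formula[i]
    p('      <species id="', sbml_id(model$mets$id[i], "M_"),
      '" name="', esc(model$mets$name[i]),
      '" compartment="', model$mets$compartment[i],
      '" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"',
      if (nzchar(frm) && !is.na(frm)) paste0(' fbc:chemicalFormula="', frm, '"'),
      '/>')
  }
  p('    </listOfSpecies>')
  p('    <listOfParameters>')
  for (v in bounds)
    p('      <parameter id="', bnd_id(v), '" value="',
      format(v, scientific = FALSE), '" constant="true"/>')
  p('    </listOfParameters>')
  p('    <listOfReactions>')
  for (j in seq_len(nrow(model$rxns))) {
    s <- model$S[, j]
    s <- s[s != 0]
    p('      <reaction id="', sbml_id(model$rxns$id[j], "R_"),
      '" name="', esc(model$rxns$name[j]),
      '" reversible="', tolower(model$rxns$lb[j] < 0), '" fast="false"',
      ' fbc:lowerFluxBound="', bnd_id(model$rxns$lb[j]),
      '" fbc:upperFluxBound="', bnd_id(model$rxns$ub[j]), '">')
    subs <- s[s < 0]; prods <- s[s > 0]
    if (length(subs) > 0L) {
      p('        <listOfReactants>')
      for (k in seq_along(subs))
        p('          <speciesReference species="',
          sbml_id(names(subs)[k], "M_"), '" stoichiometry="',
          format(-subs[k]), '" constant="true"/>')
      p('        </listOfReactants>')
    }
    if (length(prods) > 0L) {
      p('        <listOfProducts>')
      for (k in seq_along(prods))
        p('          <speciesReference species="',
          sbml_id(names(prods)[k], "M_"), '" stoichiometry="',
          format(prods[k]), '" constant="true"/>')
      p('        </listOfProducts>')
    }
    p('      </reaction>')
  }
  p('    </listOfReactions>')
  if (!is.null(model$biomass_id)) {
    p('    <fbc:listOfObjectives fbc:activeObjective="obj">')
    p('      <fbc:objective fbc:id="obj" fbc:type="maximize">')
    p('        <fbc:listOfFluxObjectives>')
    p('          <fbc:fluxObjective fbc:reaction="',
      sbml_id(model$biomass_id, "R_"), '" fbc:coefficient="1"/>')
    p('        </fbc:listOfFluxObjectives>')
    p('      </fbc:objective>')
    p('    </fbc:listOfObjectives>')
  }
  p('  </model>')
  p('</sbml>')
  writeLines(ln, path)
  invisible(path)
}

#' Read a model from SBML
#'
#' @param path SBML file (Level 2 with COBRA kinetic-law bounds, or Level 3
#'   with fbc bounds).
#' @param biomass_id optional explicit biomass reaction id (without the
#'   \code{R_} prefix); by default the fbc active objective is used, falling
#'   back to an id matching \code{"biomass"}.
#' @param ngam_id id of the ATP maintenance reaction if present
#'   (default \code{"ATPM"} when such a reaction exists).
#' @return a \code{metabolic_model}.
#' @export
read_sbml <- function(path, biomass_id = NULL, ngam_id = NULL) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("SBML parse failure in '", path, "': ", conditionMessage(e)))
  strip <- function(x, pre) sub(paste0("^", pre), "", x)
  attr1 <- function(node, what) {
    v <- xml2::xml_attr(node, what)
    v
  }
  sp_nodes <- xml2::xml_find_all(doc, "//*[local-name()='listOfSpecies']/*[local-name()='species']")
  if (length(sp_nodes) == 0L) stop("SBML format error: no species in '", path, "'")
  sp_id_raw <- xml2::xml_attr(sp_nodes, "id")
  boundary <- xml2::xml_attr(sp_nodes, "boundaryCondition")
  formula <- xml2::xml_attr(sp_nodes, "chemicalFormula")
  formula[is.na(formula)] <- ""
  mets <- data.frame(
    id = strip(sp_id_raw, "M_"),
    name = ifelse(is.na(xml2::xml_attr(sp_nodes, "name")),
                  strip(sp_id_raw, "M_"), xml2::xml_attr(sp_nodes, "name")),
    compartment = xml2::xml_attr(sp_nodes, "compartment"),
    formula = formula,
    stringsAsFactors = FALSE)
  boundary_ids <- sp_id_raw[!is.na(boundary) & boundary == "true"]
  keep <- !sp_id_raw %in% boundary_ids
  mets <- mets[keep, , drop = FALSE]
  sp_lookup <- stats::setNames(mets$id, sp_id_raw[keep])

  ## fbc bound parameters
  par_nodes <- xml2::xml_find_all(doc, "//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  par_val <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                             xml2::xml_attr(par_nodes, "id"))

  rx_nodes <- xml2::xml_find_all(doc, "//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  if (length(rx_nodes) == 0L) stop("SBML format error: no reactions in '", path, "'")
  n <- length(rx_nodes)
  ids <- strip(xml2::xml_attr(rx_nodes, "id"), "R_")
  nms <- xml2::xml_attr(rx_nodes, "name")
  nms[is.na(nms)] <- ids[is.na(nms)]
  S <- matrix(0, nrow(mets), n, dimnames = list(mets$id, ids))
  lb <- numeric(n); ub <- numeric(n)
  for (j in seq_len(n)) {
    node <- rx_nodes[[j]]
    for (side in c("listOfReactants", "listOfProducts")) {
      sgn <- if (side == "listOfReactants") -1 else 1
      refs <- xml2::xml_find_all(node, paste0("./*[local-name()='", side,
                                              "']/*[local-name()='speciesReference']"))
      for (ref in refs) {
        sp <- xml2::xml_attr(ref, "species")
        if (sp %in% boundary_ids) next
        if (!sp %in% names(sp_lookup))
          stop("SBML format error: reaction '", ids[j],
               "' references undeclared species '", sp, "'")
        st <- xml2::xml_attr(ref, "stoichiometry")
        st <- if (is.na(st)) 1 else as.numeric(st)
        S[sp_lookup[[sp]], j] <- S[sp_lookup[[sp]], j] + sgn * st
      }
    }
    lfb <- attr1(node, "lowerFluxBound"); ufb <- attr1(node, "upperFluxBound")
    if (!is.na(lfb) && lfb %in% names(par_val)) {
      lb[j] <- par_val[[lfb]]; ub[j] <- par_val[[ufb]]
    } else {
      kl <- xml2::xml_find_all(node, ".//*[local-name()='parameter']")
      kn <- xml2::xml_attr(kl, "id")
      kv <- as.numeric(xml2::xml_attr(kl, "value"))
      if ("LOWER_BOUND" %in% kn) lb[j] <- kv[match("LOWER_BOUND", kn)]
      else lb[j] <- if (identical(xml2::xml_attr(node, "reversible"), "false")) 0 else -1000
      if ("UPPER_BOUND" %in% kn) ub[j] <- kv[match("UPPER_BOUND", kn)]
      else ub[j] <- 1000
    }
  }
  ## reactions that consumed only boundary species may end up empty: drop
  nonempty <- colSums(abs(S)) > 0
  ids <- ids[nonempty]; nms <- nms[nonempty]
  lb <- lb[nonempty]; ub <- ub[nonempty]
  S <- S[, nonempty, drop = FALSE]

  if (is.null(biomass_id)) {
    fo <- xml2::xml_find_first(doc, "//*[local-name()='fluxObjective']")
    if (!inherits(fo, "xml_missing")) {
      biomass_id <- strip(xml2::xml_attr(fo, "reaction"), "R_")
    } else {
      hit <- grep("biomass", ids, ignore.case = TRUE, value = TRUE)
      if (length(hit) > 0L) biomass_id <- hit[1]
    }
  }
  if (is.null(biomass_id) || !biomass_id %in% ids)
    stop("SBML configuration error: no biomass objective found in '",
         path, "'")
  if (is.null(ngam_id) && "ATPM" %in% ids) ngam_id <- "ATPM"
  rxns <- data.frame(id = ids, name = nms, lb = lb, ub = ub,
                     stringsAsFactors = FALSE)
  metabolic_model(mets, rxns, S, biomass_id = biomass_id, ngam_id = ngam_id)
}
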