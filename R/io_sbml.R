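#' @title SBML Level 3 + FBC import/export
#' @description Reader and writer for the constraint-based subset of SBML
#'   Level 3 Version 1 with the Flux Balance Constraints (FBC) version 2
#'   package: compartments, species with chemical formulas, reactions with
#'   parameter-encoded flux bounds, gene-product associations, and the active
#'   objective. Level 2 files with note/kinetic-law-encoded bounds are read
#'   with defaults and a warning. Unsupported constructs (events, rules) are
#'   ignored, not fatal.
#' @name io-sbml
NULL

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

sbml_id <- function(prefix, id) paste0(prefix, gsub("[^A-Za-z0-9_]", "_", id))

#' Write a model as SBML Level 3 + FBC v2
#'
#' @param model A `gem`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  validate_gem(model)
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  num <- function(x) formatC(x, format = "g", digits = 15)
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1"',
                   ' fbc:required="false">'), SBML_NS, FBC_NS),
    sprintf('  <model id="%s" fbc:strict="false">', sbml_id("", model$id)),
    '    <listOfCompartments>',
    sprintf('      <compartment id="%s" name="%s" constant="true"/>',
            names(model$compartments), esc(unname(model$compartments))),
    '    </listOfCompartments>',
    '    <listOfSpecies>')
  for (i in seq_len(nrow(model$mets))) {
    m <- model$mets[i, ]
    attrs <- sprintf(paste0('id="%s" name="%s" compartment="%s" ',
                            'hasOnlySubstanceUnits="false" ',
                            'boundaryCondition="false" constant="false"'),
                     sbml_id("M_", m$id), esc(m$name), m$compartment)
    if (!is.na(m$formula)) {
      attrs <- paste0(attrs, sprintf(' fbc:chemicalFormula="%s"', m$formula))
    }
    out <- c(out, sprintf('      <species %s/>', attrs))
  }
  bounds <- sort(unique(c(model$rxns$lb, model$rxns$ub)))
  bid <- function(v) sprintf("bnd_%d", match(v, bounds))
  out <- c(out, '    </listOfSpecies>', '    <listOfParameters>',
           sprintf('      <parameter id="%s" value="%s" constant="true"/>',
                   bid(bounds), num(bounds)),
           '    </listOfParameters>', '    <listOfReactions>')
  gpr_xml <- function(tree, indent) {
    pad <- strrep(" ", indent)
    if (is.character(tree)) {
      return(sprintf('%s<fbc:geneProductRef fbc:geneProduct="%s"/>', pad,
                     sbml_id("G_", tree)))
    }
    tag <- if (tree$op == "and") "fbc:and" else "fbc:or"
    c(sprintf("%s<%s>", pad, tag),
      unlist(lapply(tree$args, gpr_xml, indent = indent + 2)),
      sprintf("%s</%s>", pad, tag))
  }
  for (i in seq_len(nrow(model$rxns))) {
    r <- model$rxns[i, ]
    st <- model$stoich[model$stoich$rxn == r$id, , drop = FALSE]
    out <- c(out, sprintf(paste0('      <reaction id="%s" name="%s" ',
                                 'reversible="%s" fast="false" ',
                                 'fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">'),
                          sbml_id("R_", r$id), esc(r$name),
                          tolower(r$lb < 0), bid(r$lb), bid(r$ub)))
    tree <- parse_gpr(r$gpr)
    if (!is.null(tree)) {
      out <- c(out, '        <fbc:geneProductAssociation>',
               gpr_xml(tree, 10), '        </fbc:geneProductAssociation>')
    }
    for (side in c(-1, 1)) {
      rows <- st[sign(st$coef) == side, , drop = FALSE]
      if (!nrow(rows)) next
      tag <- if (side < 0) "listOfReactants" else "listOfProducts"
      out <- c(out, sprintf('        <%s>', tag),
               sprintf(paste0('          <speciesReference species="%s" ',
                              'stoichiometry="%s" constant="true"/>'),
                       sbml_id("M_", rows$met), num(abs(rows$coef))),
               sprintf('        </%s>', tag))
    }
    out <- c(out, '      </reaction>')
  }
  out <- c(out, '    </listOfReactions>')
  if (!is.na(model$objective)) {
    out <- c(out,
      '    <fbc:listOfObjectives fbc:activeObjective="obj">',
      '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
      '        <fbc:listOfFluxObjectives>',
      sprintf(paste0('          <fbc:fluxObjective fbc:reaction="%s"',
                     ' fbc:coefficient="1"/>'), sbml_id("R_", model$objective)),
      '        </fbc:listOfFluxObjectives>',
      '      </fbc:objective>',
      '    </fbc:listOfObjectives>')
  }
  if (length(model$genes)) {
    out <- c(out, '    <fbc:listOfGeneProducts>',
             sprintf('      <fbc:geneProduct fbc:id="%s" fbc:label="%s"/>',
                     sbml_id("G_", model$genes), esc(model$genes)),
             '    </fbc:listOfGeneProducts>')
  }
  out <- c(out, '  </model>', '</sbml>')
  writeLines(out, path)
  invisible(path)
}

#' Read an SBML model
#'
#' Supports the Level 3 + FBC v2 subset written by [write_sbml()] (and by
#' standard constraint-based tools); missing flux bounds fall back to the
#' usual -1000/0/1000 defaults with a warning, using the `reversible`
#' attribute for the lower bound.
#'
#' @param path SBML file.
#' @return A `gem`.
#' @export
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)  # work positionally; fbc attrs keep their prefix
  mdl <- xml2::xml_find_first(doc, ".//model")
  strip <- function(x, prefix) sub(paste0("^", prefix), "", x)
  attr1 <- function(node, name) {
    v <- xml2::xml_attr(node, name)
    v
  }
  comps <- xml2::xml_find_all(mdl, ".//listOfCompartments/compartment")
  compartments <- setNames(
    ifelse(is.na(xml2::xml_attr(comps, "name")), xml2::xml_attr(comps, "id"),
           xml2::xml_attr(comps, "name")),
    xml2::xml_attr(comps, "id"))
  sp <- xml2::xml_find_all(mdl, ".//listOfSpecies/species")
  mets <- data.frame(
    id = strip(xml2::xml_attr(sp, "id"), "M_"),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")),
                  strip(xml2::xml_attr(sp, "id"), "M_"),
                  xml2::xml_attr(sp, "name")),
    compartment = xml2::xml_attr(sp, "compartment"),
    formula = xml2::xml_attr(sp, "chemicalFormula"),
    mw = NA_real_, stringsAsFactors = FALSE)
  ok <- !is.na(mets$formula)
  mets$mw[ok] <- vapply(mets$formula[ok], function(f)
    tryCatch(molecular_weight(f), error = function(e) NA_real_), numeric(1))
  pars <- xml2::xml_find_all(mdl, ".//listOfParameters/parameter")
  parval <- setNames(as.numeric(xml2::xml_attr(pars, "value")),
                     xml2::xml_attr(pars, "id"))
  gp <- xml2::xml_find_all(mdl, ".//*[local-name()='geneProduct']")
  gene_label <- setNames(
    ifelse(is.na(xml2::xml_attr(gp, "label")),
           strip(xml2::xml_attr(gp, "id"), "G_"), xml2::xml_attr(gp, "label")),
    xml2::xml_attr(gp, "id"))
  gpr_from_node <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      gid <- xml2::xml_attr(node, "geneProduct")
      lbl <- if (gid %in% names(gene_label)) gene_label[[gid]] else strip(gid, "G_")
      return(lbl)
    }
    kids <- xml2::xml_children(node)
    parts <- vapply(kids, function(k) {
      sub <- gpr_from_node(k)
      if (grepl(" ", sub)) paste0("(", sub, ")") else sub
    }, character(1))
    paste(parts, collapse = paste0(" ", nm, " "))
  }
  rx <- xml2::xml_find_all(mdl, ".//listOfReactions/reaction")
  missing_bounds <- FALSE
  rxns <- list(); stoich <- list()
  for (node in rx) {
    id <- strip(xml2::xml_attr(node, "id"), "R_")
    lb_id <- attr1(node, "lowerFluxBound"); ub_id <- attr1(node, "upperFluxBound")
    reversible <- identical(xml2::xml_attr(node, "reversible"), "true")
    lb <- if (!is.na(lb_id) && lb_id %in% names(parval)) parval[[lb_id]] else {
      missing_bounds <- TRUE; if (reversible) -1000 else 0
    }
    ub <- if (!is.na(ub_id) && ub_id %in% names(parval)) parval[[ub_id]] else {
      missing_bounds <- TRUE; 1000
    }
    ga <- xml2::xml_find_first(node, "./*[local-name()='geneProductAssociation']/*")
    gpr <- if (inherits(ga, "xml_node")) gpr_from_node(ga) else NA_character_
    rxns[[id]] <- data.frame(
      id = id,
      name = ifelse(is.na(xml2::xml_attr(node, "name")), id,
                    xml2::xml_attr(node, "name")),
      lb = lb, ub = ub, gpr = gpr, subsystem = NA_character_,
      pseudo = FALSE, stringsAsFactors = FALSE)
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(node, sprintf("./%s/speciesReference", side))
      if (!length(refs)) next
      coef <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      coef[is.na(coef)] <- 1
      stoich[[paste(id, side)]] <- data.frame(
        rxn = id, met = strip(xml2::xml_attr(refs, "species"), "M_"),
        coef = if (side == "listOfReactants") -coef else coef,
        stringsAsFactors = FALSE)
    }
  }
  if (missing_bounds) {
    warning("flux bounds missing for some reactions; defaults applied",
            call. = FALSE)
  }
  objective <- NA_character_
  fo <- xml2::xml_find_first(mdl, ".//*[local-name()='fluxObjective']")
  if (inherits(fo, "xml_node")) {
    objective <- strip(xml2::xml_attr(fo, "reaction"), "R_")
  }
  new_gem(id = xml2::xml_attr(mdl, "id"),
          compartments = compartments, mets = mets,
          rxns = do.call(rbind, rxns), stoich = do.call(rbind, stoich),
          genes = sort(unname(gene_label)), objective = objective)
}
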