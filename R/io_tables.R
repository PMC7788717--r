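#' @title Medium specifications and tabular outputs
#' @name io-tables
NULL

#' Compound registry
#'
#' Formulas for the compounds that appear in the growth media, so medium
#' files may reference compounds by name alone.
#'
#' @return Named character vector, compound -> elemental formula.
#' @export
compound_registry <- function() {
  c(glycerol = "C3H8O3", glucose = "C6H12O6", fructose = "C6H12O6",
    sucrose = "C12H22O11", xylose = "C5H10O5", ethanol = "C2H6O",
    urea = "CH4N2O", nh4cl = "NH4Cl", ammonium = "H4N")
}

#' Construct a medium specification
#'
#' @param compounds Data frame with columns `id`, optional `formula` (filled
#'   from [compound_registry()] when absent), and exactly one of `conc_g_l`
#'   (concentration in g/l) or `uptake` (mmol/gDCW/h) per row; optional
#'   `role` (`"carbon"`, `"nitrogen"`, `"other"`).
#' @return Object of class `medium_spec`.
#' @export
medium_spec <- function(compounds) {
  compounds <- as.data.frame(compounds, stringsAsFactors = FALSE)
  defaults <- list(formula = NA_character_, conc_g_l = NA_real_,
                   uptake = NA_real_, role = NA_character_)
  for (col in names(defaults)) {
    if (!col %in% names(compounds)) {
      compounds[[col]] <- rep(defaults[[col]], nrow(compounds))
    }
  }
  reg <- compound_registry()
  fill <- is.na(compounds$formula) & compounds$id %in% names(reg)
  compounds$formula[fill] <- reg[compounds$id[fill]]
  if (nrow(compounds) &&
      any(is.na(compounds$conc_g_l) & is.na(compounds$uptake))) {
    stop("each compound needs a concentration or an uptake rate", call. = FALSE)
  }
  structure(list(compounds = compounds), class = "medium_spec")
}

#' @export
print.medium_spec <- function(x, ...) {
  cat("<medium_spec>", nrow(x$compounds), "compound(s)\n")
  print(x$compounds)
  invisible(x)
}

#' Read a medium file
#'
#' YAML files carry a `compounds` list with `id` and `conc_g_l` or `uptake`
#' (and optional `formula`, `role`); two-column TSV files are read as
#' `id<TAB>conc_g_l`. An empty file yields an empty, valid medium.
#'
#' @param path Medium file (`.yml`/`.yaml` or `.tsv`).
#' @return A [medium_spec()].
#' @export
read_medium <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    doc <- yaml::read_yaml(path)
    if (is.null(doc) || is.null(doc$compounds) || !length(doc$compounds)) {
      return(medium_spec(data.frame(id = character())))
    }
    rows <- lapply(doc$compounds, function(x) {
      data.frame(id = x$id,
                 formula = if (is.null(x$formula)) NA_character_ else x$formula,
                 conc_g_l = if (is.null(x$conc_g_l)) NA_real_ else x$conc_g_l,
                 uptake = if (is.null(x$uptake)) NA_real_ else x$uptake,
                 role = if (is.null(x$role)) NA_character_ else x$role,
                 stringsAsFactors = FALSE)
    })
    return(medium_spec(do.call(rbind, rows)))
  }
  tab <- tryCatch(
    utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                      comment.char = "#"),
    error = function(e) NULL)
  if (is.null(tab) || !nrow(tab)) {
    return(medium_spec(data.frame(id = character())))
  }
  medium_spec(data.frame(id = tab[[1]], conc_g_l = as.numeric(tab[[2]]),
                         stringsAsFactors = FALSE))
}

#' Total elemental molarities of a medium
#'
#' @param medium A `medium_spec` with concentrations.
#' @return Named vector of mol/l per element.
#' @export
medium_molarity <- function(medium) {
  tab <- medium$compounds
  if (!nrow(tab)) return(setNames(numeric(0), character(0)))
  em <- element_matrix(tab$formula)
  mol <- tab$conc_g_l / vapply(tab$formula, molecular_weight, numeric(1))
  colSums(em * mol)
}

#' Write fluxes, sampling summaries or Z-scores as TSV
#'
#' Deterministic column order and 6-significant-digit floats, so repeated
#' runs produce byte-identical files.
#'
#' @param x A `flux_solution`, `sampling_result`, `zscore_table`, or a data
#'   frame.
#' @param path Output TSV path.
#' @param model Optional `gem` supplying subsystem annotations.
#' @return `path`, invisibly.
#' @export
write_flux_table <- function(x, path, model = NULL) {
  tab <- if (inherits(x, "flux_solution")) {
    data.frame(rxn = names(x$fluxes), flux = unname(x$fluxes),
               stringsAsFactors = FALSE)
  } else if (inherits(x, "sampling_result")) {
    summary(x)
  } else if (inherits(x, "zscore_table") || is.data.frame(x)) {
    as.data.frame(x)
  } else {
    stop("unsupported object for write_flux_table", call. = FALSE)
  }
  if (!is.null(model) && "rxn" %in% names(tab) && !"subsystem" %in% names(tab)) {
    tab$subsystem <- model$rxns$subsystem[match(tab$rxn, model$rxns$id)]
    tab <- tab[, c("rxn", "subsystem",
                   setdiff(names(tab), c("rxn", "subsystem")))]
  }
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(v) formatC(v, format = "g", digits = 6))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
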