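#' @title Condition-specific biomass objective function
#' @description The carbon-to-nitrogen ratio of the medium (or of the uptake
#'   rates) drives the macromolecular composition of an oleaginous yeast:
#'   under nitrogen starvation the carbohydrate fraction is pinned at 11% of
#'   dry cell weight, 5% is nucleic acids/minerals/cofactors, and protein and
#'   total lipid share the remaining 95%, with the lipid fraction following a
#'   quadratic function of C/N (g/g) fitted to chemostat data. The biomass
#'   reaction assembled from a composition is standardized to a molecular
#'   weight of 1 g/mmol, so its flux is the specific growth rate in 1/h.
#' @name biomass-builder
NULL

#' C/N ratio container
#'
#' @param molar mol C / mol N.
#' @return Object of class `cn_ratio` with fields `molar` and `mass`
#'   (g C / g N = molar x 12.011 / 14.007); both are `Inf` when the medium
#'   has no nitrogen.
#' @export
cn_ratio <- function(molar) {
  stopifnot(is.numeric(molar), length(molar) == 1L)
  if (!is.infinite(molar) && molar < 0) stop("negative C/N ratio", call. = FALSE)
  structure(list(molar = molar, mass = cn_molar_to_mass(molar)),
            class = "cn_ratio")
}

#' @export
print.cn_ratio <- function(x, ...) {
  cat(sprintf("C/N = %.4g mol/mol = %.4g g/g\n", x$molar, x$mass))
  invisible(x)
}

#' Convert a molar C/N ratio to a mass ratio
#'
#' @param x C/N in mol C / mol N (>= 0).
#' @return C/N in g C / g N, i.e. `x * 12.011 / 14.007`. The critical molar
#'   ratio of 12.83 maps to 11 g/g.
#' @export
cn_molar_to_mass <- function(x) {
  if (any(!is.infinite(x) & x < 0)) stop("negative C/N ratio", call. = FALSE)
  x * ATOMIC_MASSES[["C"]] / ATOMIC_MASSES[["N"]]
}

#' C/N ratio of a medium
#'
#' Works identically on concentrations (g/l) and on uptake rates
#' (mmol/gDCW/h): the per-litre or per-hour basis cancels in the ratio.
#' For concentrations, moles are concentration / molecular weight; for uptake
#' rates the amounts are already molar.
#'
#' @param medium A `medium_spec` (see [read_medium()] / [medium_spec()]).
#' @return A [cn_ratio]. `Inf` with a warning when no nitrogen is supplied.
#' @export
cn_ratio_from_medium <- function(medium) {
  stopifnot(inherits(medium, "medium_spec"))
  tab <- medium$compounds
  if (!nrow(tab)) stop("empty medium", call. = FALSE)
  if (any(is.na(tab$formula) | !nzchar(tab$formula))) {
    stop("compound(s) without formula: ",
         paste(tab$id[is.na(tab$formula) | !nzchar(tab$formula)], collapse = ", "),
         call. = FALSE)
  }
  em <- element_matrix(tab$formula)
  cs <- if ("C" %in% colnames(em)) em[, "C"] else numeric(nrow(tab))
  ns <- if ("N" %in% colnames(em)) em[, "N"] else numeric(nrow(tab))
  mol <- ifelse(is.na(tab$conc_g_l),
                tab$uptake,
                tab$conc_g_l / vapply(tab$formula, molecular_weight, numeric(1)))
  molC <- sum(mol * cs); molN <- sum(mol * ns)
  if (molC <= 0) stop("medium supplies no carbon", call. = FALSE)
  if (molN <= 0) {
    warning("medium supplies no nitrogen; C/N ratio is infinite", call. = FALSE)
    return(cn_ratio(Inf))
  }
  cn_ratio(molC / molN)
}

#' C/N ratio implied by a pair of uptake rates
#'
#' Elemental compositions are taken from the formulas of the exchanged
#' metabolites in the model.
#'
#' @param model A `gem`.
#' @param carbon_exchange,nitrogen_exchange Exchange reaction ids.
#' @param carbon_uptake,nitrogen_uptake Uptake magnitudes (mmol/gDCW/h).
#' @return A [cn_ratio].
#' @export
cn_ratio_from_uptakes <- function(model, carbon_exchange, nitrogen_exchange,
                                  carbon_uptake, nitrogen_uptake) {
  atoms <- function(ex, element) {
    mets <- model$stoich$met[model$stoich$rxn == ex]
    if (length(mets) != 1L) stop("not a single-species exchange: ", ex, call. = FALSE)
    f <- model$mets$formula[match(mets, model$mets$id)]
    if (is.na(f)) stop("exchanged species has no formula: ", mets, call. = FALSE)
    counts <- parse_formula(f)
    if (element %in% names(counts)) counts[[element]] else 0
  }
  molC <- carbon_uptake * atoms(carbon_exchange, "C")
  molN <- nitrogen_uptake * atoms(nitrogen_exchange, "N")
  if (molC <= 0) stop("carbon exchange supplies no carbon", call. = FALSE)
  if (molN <= 0) return(cn_ratio(Inf))
  cn_ratio(molC / molN)
}

#' Lipid content as a function of C/N (g/g)
#'
#' Quadratic fit of total lipid (% of dry cell weight) against the C/N mass
#' ratio: `y = -0.002 x^2 + 0.59 x + 1.9`, evaluated on C/N in g/g and
#' clamped to `[0, 79]` so that the protein fraction stays non-negative given
#' 11% carbohydrate and 5% other. The vertex (global maximum 45.41%) is at
#' x = 147.5; beyond it the polynomial decreases as fitted — no plateau is
#' imposed.
#'
#' @param cn_gg C/N in g/g (vectorized, >= 0).
#' @param coefficients Quadratic coefficients `(a, b, c)`.
#' @return Total lipid in % of DCW.
#' @export
lipid_weight_percent <- function(cn_gg, coefficients = c(a = -0.002, b = 0.59, c = 1.9)) {
  if (any(cn_gg < 0)) stop("C/N must be non-negative", call. = FALSE)
  x <- pmin(cn_gg, 1e6)  # guard Inf: far beyond the vertex the clamp is 0 anyway
  y <- coefficients[[1]] * x^2 + coefficients[[2]] * x + coefficients[[3]]
  pmin(pmax(y, 0), 79)
}

#' Macromolecular biomass composition at a C/N ratio
#'
#' Starvation mode: carbohydrate fixed at 11% of DCW, "other" (nucleic acids,
#' minerals, cofactors) at 5%, total lipid from [lipid_weight_percent()], and
#' protein takes the remainder of the 95%. Replete mode returns the static
#' nitrogen-abundant composition (40% carbohydrate, 45% protein, 10% lipid,
#' 5% other by default; configurable).
#'
#' @param cn_gg C/N in g/g.
#' @param mode `"starvation"` or `"replete"`.
#' @param replete Replete-mode fractions `(w_C, w_P, w_TL, w_other)`.
#' @return Object of class `biomass_composition`: weight fractions `w_C`,
#'   `w_P`, `w_TL`, `w_other` (summing to 1), `mode`, `cn_gg`, and the lipid
#'   profile (`tag_fraction` 0.90, phospholipids in equal thirds).
#' @export
compose_biomass <- function(cn_gg, mode = c("starvation", "replete"),
                            replete = c(w_C = 0.40, w_P = 0.45,
                                        w_TL = 0.10, w_other = 0.05)) {
  mode <- match.arg(mode)
  if (mode == "starvation") {
    w_TL <- lipid_weight_percent(cn_gg) / 100
    w_C <- 0.11; w_other <- 0.05
    w_P <- 0.95 - w_C - w_TL
    stopifnot(w_P >= 0)  # guaranteed by the [0, 79] clamp
  } else {
    w_C <- replete[["w_C"]]; w_P <- replete[["w_P"]]
    w_TL <- replete[["w_TL"]]; w_other <- replete[["w_other"]]
  }
  out <- list(w_C = w_C, w_P = w_P, w_TL = w_TL, w_other = w_other,
              mode = mode, cn_gg = cn_gg,
              tag_fraction = 0.90,
              phospholipid_fractions = c(ps = 1, pe = 1, pc = 1) / 3 * 0.10)
  stopifnot(abs(out$w_C + out$w_P + out$w_TL + out$w_other - 1) < 1e-12)
  structure(out, class = "biomass_composition")
}

#' @export
print.biomass_composition <- function(x, ...) {
  cat(sprintf("biomass composition (%s, C/N = %.3g g/g):\n", x$mode, x$cn_gg))
  cat(sprintf("  carbohydrate %.1f%%  protein %.1f%%  total lipid %.1f%%  other %.1f%%\n",
              100 * x$w_C, 100 * x$w_P, 100 * x$w_TL, 100 * x$w_other))
  invisible(x)
}

#' The acyl-CoA pool reaction
#'
#' An artificial reaction lumping the activated fatty acids into a single
#' lipid-building precursor. Each coefficient is the weight fraction of that
#' fatty acid in total lipid divided by the molecular weight of its CoA
#' thioester in g/mmol, i.e. mmol of acyl-CoA per gram of pool:
#' `0.24952 C16:0-CoA + 0.096712 C18:0-CoA + 0.55233 C18:1-CoA +
#' 0.067963 C18:2-CoA -> acyl-CoA pool`.
#'
#' @param mets Metabolite ids of the four acyl-CoA species, in the order
#'   C16:0, C18:0, C18:1, C18:2 (defaults match the bundled toy model).
#' @return Data frame `species`, `met`, `coef` (substrate-side magnitudes).
#' @export
acyl_pool_reaction <- function(mets = c("pmtcoa_c", "stcoa_c", "odecoa_c",
                                        "lnlccoa_c")) {
  data.frame(
    species = c("C16:0-CoA", "C18:0-CoA", "C18:1-CoA", "C18:2-CoA"),
    met = mets,
    coef = c(0.24952, 0.096712, 0.55233, 0.067963),
    stringsAsFactors = FALSE)
}

#' Fatty-acid weight shares of the acyl-CoA pool
#'
#' Multiplying each pool coefficient (mmol per g of pool) by the molecular
#' weight of the corresponding acyl-CoA (g/mmol) recovers the fatty-acid
#' weight percentages of total lipid: 25/10/57/7 at printed precision
#' (summing to 99%).
#'
#' @param mw Molecular weights of the four acyl-CoAs in g/mol; defaults are
#'   computed from the standard thioester formulas.
#' @return Named numeric vector of weight shares in percent.
#' @export
acyl_pool_fractions <- function(mw = c(molecular_weight("C37H62N7O17P3S"),
                                       molecular_weight("C39H66N7O17P3S"),
                                       molecular_weight("C39H64N7O17P3S"),
                                       molecular_weight("C39H62N7O17P3S"))) {
  pool <- acyl_pool_reaction()
  setNames(100 * pool$coef * mw / 1000,
           c("C16:0", "C18:0", "C18:1", "C18:2"))
}

#' Assemble the biomass reaction for a composition
#'
#' Each macromolecular component enters with stoichiometric coefficient
#' weight fraction / component MW (g/mmol), so the summed coefficient-times-
#' MW product is exactly 1 g/mmol per unit of biomass. Growth-associated
#' maintenance is added as GAM ATP hydrolysis.
#'
#' @param composition A `biomass_composition`.
#' @param model A `gem` containing the pseudo-species `carb_c`, `prot_c`,
#'   `lipid_c`, `other_c` (with annotated molecular weights) plus
#'   `biomass_c`, `atp_c`, `h2o_c`, `adp_c`, `pi_c`, `h_c`.
#' @param gam Growth-associated maintenance, mmol ATP per g biomass.
#' @return Data frame of stoichiometry (`met`, `coef`) for the biomass
#'   reaction, attribute `"mw"` carrying the implied biomass MW in g/mmol.
#' @export
assemble_biomass_reaction <- function(composition, model, gam = 60) {
  stopifnot(inherits(composition, "biomass_composition"))
  comp_mets <- c(carbohydrate = "carb_c", protein = "prot_c",
                 lipid = "lipid_c", other = "other_c")
  aux <- c("biomass_c", "atp_c", "h2o_c", "adp_c", "pi_c", "h_c")
  missing <- setdiff(c(comp_mets, aux), model$mets$id)
  if (length(missing)) {
    stop("model lacks biomass species: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  mw <- model$mets$mw[match(comp_mets, model$mets$id)] / 1000  # g/mmol
  if (anyNA(mw) || any(mw <= 0)) {
    stop("biomass components need annotated molecular weights", call. = FALSE)
  }
  w <- c(composition$w_C, composition$w_P, composition$w_TL, composition$w_other)
  coef <- w / mw
  stoich <- data.frame(
    met = c(unname(comp_mets), "atp_c", "h2o_c", "biomass_c", "adp_c", "pi_c", "h_c"),
    coef = c(-coef, -gam, -gam, 1, gam, gam, gam),
    stringsAsFactors = FALSE)
  stoich <- stoich[stoich$coef != 0, ]
  attr(stoich, "mw") <- sum(coef * mw)
  attr(stoich, "composition") <- composition
  stoich
}

#' Install a condition-specific biomass reaction in a model
#'
#' Replaces the stoichiometry of the model's biomass reaction with the one
#' assembled from `composition`.
#'
#' @inheritParams assemble_biomass_reaction
#' @param rxn Biomass reaction id (defaults to the model objective).
#' @return Modified model.
#' @export
install_biomass <- function(model, composition, gam = 60, rxn = model$objective) {
  stoich <- assemble_biomass_reaction(composition, model, gam = gam)
  keep <- model$stoich$rxn != rxn
  add <- data.frame(rxn = rxn, met = stoich$met, coef = stoich$coef,
                    stringsAsFactors = FALSE)
  model$stoich <- rbind(model$stoich[keep, ], add)
  rownames(model$stoich) <- NULL
  validate_gem(model)
}

#' Molecular weight implied by an assembled biomass reaction
#'
#' Recomputes the coefficient-times-MW sum over the macromolecular
#' components from the model's stoichiometry (not from the stored
#' composition), in g/mmol. Equals 1 within numerical tolerance for any
#' composition assembled by this package.
#'
#' @param model A `gem` with an installed biomass reaction.
#' @param rxn Biomass reaction id.
#' @return Implied biomass molecular weight, g/mmol.
#' @export
biomass_mw <- function(model, rxn = model$objective) {
  comp <- c("carb_c", "prot_c", "lipid_c", "other_c")
  rows <- model$stoich[model$stoich$rxn == rxn & model$stoich$met %in% comp, ]
  if (!nrow(rows)) stop("no biomass components in reaction ", rxn, call. = FALSE)
  mw <- model$mets$mw[match(rows$met, model$mets$id)] / 1000
  sum(-rows$coef * mw)
}

#' Recover the macromolecular composition from an installed biomass reaction
#'
#' Inverse of [assemble_biomass_reaction()]: coefficients times component
#' molecular weights give back the weight fractions.
#'
#' @inheritParams biomass_mw
#' @return Named numeric vector `(w_C, w_P, w_TL, w_other)`.
#' @export
composition_from_reaction <- function(model, rxn = model$objective) {
  comp <- c(w_C = "carb_c", w_P = "prot_c", w_TL = "lipid_c", w_other = "other_c")
  rows <- model$stoich[model$stoich$rxn == rxn, ]
  idx <- match(comp, rows$met)
  if (anyNA(idx)) stop("biomass reaction lacks components", call. = FALSE)
  mw <- model$mets$mw[match(comp, model$mets$id)] / 1000
  setNames(-rows$coef[idx] * mw, names(comp))
}

#' Weight breakdown of the lipid fraction in a model
#'
#' Reads the lipid-pool reaction and reports each lipid class's mass share of
#' the total lipid pseudo-species (TAG 90%, PS/PE/PC equal thirds of 10% in
#' the bundled model), computed from the reaction coefficients and component
#' molecular weights.
#'
#' @param model A `gem` with a `LIPIDPOOL` reaction.
#' @param rxn Lipid-pool reaction id.
#' @return Named numeric vector of percentages (substrate side).
#' @export
biomass_lipid_breakdown <- function(model, rxn = "LIPIDPOOL") {
  rows <- model$stoich[model$stoich$rxn == rxn & model$stoich$coef < 0, ]
  if (!nrow(rows)) stop("no lipid-pool reaction ", rxn, call. = FALSE)
  mw <- model$mets$mw[match(rows$met, model$mets$id)] / 1000
  mass <- -rows$coef * mw
  setNames(100 * mass / sum(mass), rows$met)
}
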