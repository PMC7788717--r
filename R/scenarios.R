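#' @title Scenario runners
#' @description Reproduce the figure-level experiments at configurable scale:
#'   the C/N grid contrasting the condition-specific (dynamic) against the
#'   static biomass, the carbon-source growth/lipid screens at equal C-mol,
#'   and the acetyl-CoA flux-trend series with urea as nitrogen source. The
#'   scripts under `analysis/` are thin drivers over these functions.
#' @name scenarios
NULL

#' Lipid production over a carbon x nitrogen uptake grid
#'
#' For every grid cell the carbon uptake is fixed, nitrogen offered, the
#' biomass reaction installed (condition-specific in dynamic mode, the
#' static nitrogen-replete composition otherwise), and the lipid-production
#' protocol run. Three lipid measures are reported: the maximized lipid-body
#' export, the biomass-embedded lipid production (biomass flux times lipid
#' weight fraction), and their sum (total lipid synthesis, the flux through
#' the lipid pool).
#'
#' @param model A `gem`.
#' @param c_uptakes,n_uptakes Uptake grids (mmol/gDCW/h).
#' @param carbon_exchange,nitrogen_exchange Exchange reaction ids.
#' @param dynamic_biomass Condition-specific (TRUE) or static biomass.
#' @param gam Growth-associated maintenance.
#' @return Data frame: `c_uptake`, `n_uptake`, `cn_gg`, `mu_star`,
#'   `lipid_export`, `lipid_biomass`, `lipid_total`, `feasible`.
#' @export
scenario_cn_grid <- function(model, c_uptakes, n_uptakes,
                             carbon_exchange = "EX_glc",
                             nitrogen_exchange = "EX_nh4",
                             dynamic_biomass = TRUE, gam = 60) {
  model <- set_minimal_medium(model)
  rows <- list()
  for (cu in c_uptakes) {
    for (nu in n_uptakes) {
      cond <- apply_cn_condition(model, carbon_exchange, nitrogen_exchange,
                                 cu, nu, dynamic_biomass, gam)
      pr <- lipid_production_protocol(cond$model)
      w_TL <- if (dynamic_biomass) {
        compose_biomass(cond$cn$mass, mode = "starvation")$w_TL
      } else {
        compose_biomass(cond$cn$mass, mode = "replete")$w_TL
      }
      biomass_flux <- if (!is.null(pr$solution)) {
        pr$solution$fluxes[[cond$model$objective]]
      } else 0
      lipid_biomass <- biomass_flux * w_TL  # mmol/gDCW/h at MW 1 g/mmol
      rows[[length(rows) + 1L]] <- data.frame(
        c_uptake = cu, n_uptake = nu, cn_gg = cond$cn$mass,
        mu_star = pr$mu_star, lipid_export = pr$lipid_flux,
        lipid_biomass = lipid_biomass,
        lipid_total = pr$lipid_flux + lipid_biomass,
        feasible = !pr$no_growth, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Growth and lipid production per carbon source at equal C-mol
#'
#' @param model A `gem`.
#' @param sources Named vector source -> exchange id (default: the bundled
#'   model's six sources).
#' @param reference_uptake Uptake of the reference source (glucose) whose
#'   C-mol delivery every source matches.
#' @param n_uptakes Nitrogen uptakes to scan.
#' @param nitrogen_exchange Nitrogen exchange id.
#' @param dynamic_biomass Condition-specific biomass per cell?
#' @param gam Growth-associated maintenance.
#' @return Data frame: `source`, `c_uptake`, `n_uptake`, `cn_gg`, `mu`,
#'   `lipid_export`, `feasible`.
#' @export
scenario_carbon_sources <- function(model,
                                    sources = c(glucose = "EX_glc",
                                                fructose = "EX_fru",
                                                sucrose = "EX_sucr",
                                                xylose = "EX_xyl",
                                                glycerol = "EX_glyc",
                                                ethanol = "EX_etoh"),
                                    reference_uptake = 10,
                                    n_uptakes = c(1, 5),
                                    nitrogen_exchange = "EX_nh4",
                                    dynamic_biomass = TRUE, gam = 60) {
  bad <- setdiff(names(sources), names(carbon_atom_counts()))
  if (length(bad)) stop("unknown source(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  model <- set_minimal_medium(model)
  rows <- list()
  for (src in names(sources)) {
    cu <- uptake_for_equal_cmol(src, "glucose", reference_uptake)
    for (nu in n_uptakes) {
      cond <- apply_cn_condition(model, sources[[src]], nitrogen_exchange,
                                 cu, nu, dynamic_biomass, gam)
      pr <- lipid_production_protocol(cond$model)
      rows[[length(rows) + 1L]] <- data.frame(
        source = src, c_uptake = cu, n_uptake = nu, cn_gg = cond$cn$mass,
        mu = pr$mu_star, lipid_export = pr$lipid_flux,
        feasible = !pr$no_growth, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Acetyl-CoA source analysis: tracked fluxes along a C/N sweep
#'
#' Nitrogen is supplied as urea at a fixed offered uptake (the chemostat
#' setting of the acetyl-CoA experiments, 25 mmol/gDCW/h); carbon is raised
#' to realize each target C/N (g/g). At each condition the lipid protocol is
#' applied and the constrained space sampled; means and standard deviations
#' (and standard errors) of the four tracked reactions — citrate transport
#' out of the mitochondrion, ATP-citrate lyase, the acyl-CoA pool reaction,
#' and the lipid-body exchange — are reported.
#'
#' @param model A `gem` with the tracked reactions present.
#' @param cn_list Target C/N ratios (g/g).
#' @param urea_uptake Offered urea uptake (mmol/gDCW/h).
#' @param carbon_exchange Carbon-source exchange (glycerol by default).
#' @param tracked Named vector of the four tracked reaction ids.
#' @param n,seed,steps_per_point Sampler settings.
#' @param gam Growth-associated maintenance.
#' @param knockout Optional gene ids to delete before the sweep.
#' @return Long data frame: `cn_gg`, `reaction`, `mean`, `sd`, `se`, `mu_star`.
#' @export
scenario_acetylcoa <- function(model, cn_list = c(2, 4, 6, 8, 10, 12, 14, 16),
                               urea_uptake = 25,
                               carbon_exchange = "EX_glyc",
                               tracked = c(citrate_transport = "CITtcm",
                                           acl = "ACL",
                                           acyl_pool = "ACYLPOOL",
                                           lipid_exchange = "EX_lipid_body"),
                               n = 300, seed = 1, steps_per_point = 8,
                               gam = 60, knockout = NULL) {
  missing <- setdiff(tracked, model$rxns$id)
  if (length(missing)) stop("tracked reaction(s) missing: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  model <- set_minimal_medium(model)
  if (!is.null(knockout)) {
    model <- knockout_growth(model, knockout, lipid_exchange = NULL)$model
  }
  rows <- list()
  for (k in seq_along(cn_list)) {
    cn <- cn_list[k]
    uC <- carbon_uptake_for_cn(model, carbon_exchange, "EX_urea",
                               urea_uptake, cn)
    cond <- apply_cn_condition(model, carbon_exchange, "EX_urea", uC,
                               urea_uptake, dynamic_biomass = TRUE, gam = gam)
    pr <- lipid_production_protocol(cond$model)
    if (pr$no_growth) {
      rows[[k]] <- data.frame(cn_gg = cn, reaction = names(tracked),
                              mean = 0, sd = 0, se = 0, mu_star = pr$mu_star,
                              stringsAsFactors = FALSE)
      next
    }
    smp <- sample_fluxes(pr$constrained_model, n = n, seed = seed + k,
                         steps_per_point = steps_per_point)
    su <- summary(smp)
    idx <- match(tracked, su$rxn)
    rows[[k]] <- data.frame(cn_gg = cn, reaction = names(tracked),
                            mean = su$mean[idx], sd = su$sd[idx],
                            se = su$se[idx], mu_star = pr$mu_star,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Carbon uptake realizing a target C/N against a fixed nitrogen uptake
#'
#' @param model A `gem`.
#' @param carbon_exchange,nitrogen_exchange Exchange ids.
#' @param nitrogen_uptake Nitrogen-source uptake (mmol/gDCW/h).
#' @param cn_gg Target C/N (g/g).
#' @return Carbon-source uptake (mmol/gDCW/h).
#' @export
carbon_uptake_for_cn <- function(model, carbon_exchange, nitrogen_exchange,
                                 nitrogen_uptake, cn_gg) {
  atoms <- function(ex, el) {
    met <- model$stoich$met[model$stoich$rxn == ex]
    counts <- parse_formula(model$mets$formula[match(met, model$mets$id)])
    if (el %in% names(counts)) counts[[el]] else 0
  }
  gN <- nitrogen_uptake * atoms(nitrogen_exchange, "N") * ATOMIC_MASSES[["N"]]
  gC <- cn_gg * gN
  gC / (atoms(carbon_exchange, "C") * ATOMIC_MASSES[["C"]])
}
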