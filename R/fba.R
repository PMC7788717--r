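#' @title Flux balance analysis and the lipid-production protocols
#' @description Core FBA on a `gem` plus the simulation protocols used in the
#'   lipid-accumulation analyses: minimal-medium setup, equal-C-mol carbon
#'   source normalization, growth screens over uptake grids, the
#'   fixed-biomass-window lipid maximization, and gene knockouts.
#' @name fba-engine
NULL

#' Default protocol parameters
#'
#' `mu_max` is the experimentally motivated maximal growth rate (h^-1) above
#' which biomass is capped during lipid simulations; `window` the fraction of
#' the cap used as lower bound; `ngam` the non-growth-associated maintenance
#' (mmol ATP/gDCW/h); `validation_uptake` the carbon uptake used for
#' single-source growth validation; `growth_tol` the threshold below which
#' growth counts as zero.
#'
#' @return Named list of parameters.
#' @export
protocol_params <- function() {
  list(mu_max = 0.20, window = 0.9, ngam = 1,
       validation_uptake = 10, growth_tol = 1e-6)
}

#' Set flux bounds on one or more reactions
#'
#' @param model A `gem`.
#' @param rxn Reaction id(s).
#' @param lb,ub New bounds (recycled); NA leaves a bound unchanged.
#' @return Modified model.
#' @export
set_bounds <- function(model, rxn, lb = NA, ub = NA) {
  idx <- match(rxn, model$rxns$id)
  if (anyNA(idx)) {
    stop("unknown reaction(s): ", paste(rxn[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  lb <- rep_len(lb, length(idx)); ub <- rep_len(ub, length(idx))
  keep <- !is.na(lb); model$rxns$lb[idx[keep]] <- lb[keep]
  keep <- !is.na(ub); model$rxns$ub[idx[keep]] <- ub[keep]
  model
}

#' Exchange reaction ids of a model
#' @param model A `gem`.
#' @return Character vector of exchange reaction ids (structural definition).
#' @export
exchange_reactions <- function(model) {
  cls <- classify_reactions(model)$category
  names(cls)[cls == "exchange"]
}

#' Flux balance analysis
#'
#' Maximizes (or minimizes) the flux of one reaction subject to steady state
#' `S v = 0` and the model's bounds. When optimal, the solution is verified:
#' `max |S v|` must be below `check_tol` and all fluxes within bounds.
#'
#' @param model A `gem`.
#' @param objective Reaction id to optimize; defaults to the model objective.
#' @param sense `"max"` or `"min"`.
#' @param basis Optional warm-start basis from a previous solution.
#' @param check_tol Verification tolerance on the steady-state residual.
#' @return List of class `flux_solution`: `status`, `objective`, `fluxes`
#'   (named vector), `mu` (the objective flux when it is the biomass
#'   reaction), `basis`.
#' @export
fba <- function(model, objective = model$objective, sense = c("max", "min"),
                basis = NULL, check_tol = 1e-6) {
  sense <- match.arg(sense)
  if (is.na(objective) || !objective %in% model$rxns$id) {
    stop("objective reaction not in model: ", objective, call. = FALSE)
  }
  S <- stoichiometric_matrix(model)
  obj <- as.numeric(model$rxns$id == objective)
  res <- solve_lp(S, NULL, obj, model$rxns$lb, model$rxns$ub, sense = sense,
                  basis = basis)
  fluxes <- setNames(res$x, model$rxns$id)
  if (res$status == "optimal") {
    resid <- max(abs(as.numeric(S %*% res$x)))
    if (resid > check_tol) {
      stop(sprintf("FBA solution failed steady-state check (|Sv| = %.3g)", resid),
           call. = FALSE)
    }
    if (any(res$x < model$rxns$lb - 1e-6) || any(res$x > model$rxns$ub + 1e-6)) {
      stop("FBA solution violates bounds", call. = FALSE)
    }
  }
  structure(list(status = res$status, objective = res$objective,
                 fluxes = fluxes,
                 mu = if (identical(objective, model$objective)) res$objective else NA_real_,
                 basis = res$basis),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("<flux_solution> status=%s objective=%s\n", x$status,
              format(x$objective, digits = 6)))
  invisible(x)
}

#' Flux variability analysis
#'
#' Minimum and maximum attainable flux per reaction under the current bounds
#' (optionally with the objective fixed to a fraction of its optimum).
#' Successive LPs share a warm-start basis, which makes the scan fast.
#'
#' @param model A `gem`.
#' @param reactions Reaction ids to scan (default all).
#' @param fix_objective If not NULL, fraction of the optimal objective to
#'   require as a lower bound on the objective reaction before scanning.
#' @return Data frame `rxn`, `min`, `max`; attribute `"points"` holds the flux
#'   vectors of every optimum (used as sampler warmup).
#' @export
fva <- function(model, reactions = model$rxns$id, fix_objective = NULL) {
  if (!is.null(fix_objective)) {
    opt <- fba(model)
    if (opt$status != "optimal") stop("FVA: model infeasible", call. = FALSE)
    model <- set_bounds(model, model$objective, lb = fix_objective * opt$objective)
  }
  S <- as.matrix(stoichiometric_matrix(model))
  lb <- model$rxns$lb; ub <- model$rxns$ub
  n <- ncol(S)
  pts <- matrix(NA_real_, 2L * length(reactions), n,
                dimnames = list(NULL, model$rxns$id))
  out <- data.frame(rxn = reactions, min = NA_real_, max = NA_real_,
                    stringsAsFactors = FALSE)
  basis <- NULL
  for (k in seq_along(reactions)) {
    j <- match(reactions[k], model$rxns$id)
    obj <- numeric(n); obj[j] <- 1
    lo <- solve_lp(S, NULL, obj, lb, ub, sense = "min", basis = basis)
    if (lo$status != "optimal") stop("FVA subproblem ", reactions[k], ": ", lo$status,
                                     call. = FALSE)
    basis <- lo$basis
    hi <- solve_lp(S, NULL, obj, lb, ub, sense = "max", basis = basis)
    if (hi$status != "optimal") stop("FVA subproblem ", reactions[k], ": ", hi$status,
                                     call. = FALSE)
    basis <- hi$basis
    out$min[k] <- lo$objective; out$max[k] <- hi$objective
    pts[2L * k - 1L, ] <- lo$x; pts[2L * k, ] <- hi$x
  }
  attr(out, "points") <- pts
  out
}

#' Open the minimal medium
#'
#' Allows unlimited uptake of CO2, water, protons, O2, iron(II), phosphate,
#' potassium, sodium, sulphate and ammonium (exchange lower bounds -1000) and
#' closes uptake of everything else; all exchange upper bounds are 1000 so
#' secretion stays free. Carbon and nitrogen sources are opened afterwards by
#' the individual protocols.
#'
#' @param model A `gem`.
#' @param unlimited Exchange reaction ids with unconstrained uptake.
#' @return Modified model.
#' @export
set_minimal_medium <- function(model,
                               unlimited = c("EX_co2", "EX_h2o", "EX_h", "EX_o2",
                                             "EX_fe2", "EX_pi", "EX_k", "EX_na1",
                                             "EX_so4", "EX_nh4")) {
  ex <- exchange_reactions(model)
  model <- set_bounds(model, ex, lb = 0, ub = 1000)
  present <- intersect(unlimited, ex)
  missing <- setdiff(unlimited, ex)
  if (length(missing)) {
    warning("minimal medium: missing exchange(s) skipped: ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  set_bounds(model, present, lb = -1000)
}

#' Uptake rate giving equal C-mol across carbon sources
#'
#' @param source,reference_source Carbon source names (see
#'   [carbon_atom_counts()]) or numbers of carbon atoms.
#' @param reference_uptake Uptake rate of the reference source
#'   (mmol/gDCW/h, magnitude).
#' @return Uptake rate for `source` delivering the same C-mol per hour.
#' @export
uptake_for_equal_cmol <- function(source, reference_source, reference_uptake) {
  n_src <- if (is.numeric(source)) source else carbon_atom_counts()[[source]]
  n_ref <- if (is.numeric(reference_source)) reference_source
           else carbon_atom_counts()[[reference_source]]
  if (is.null(n_src) || is.null(n_ref)) stop("unknown carbon source", call. = FALSE)
  if (n_src <= 0) stop("carbon-free source: ", source, call. = FALSE)
  reference_uptake * n_ref / n_src
}

#' Carbon atoms per molecule for the supported carbon sources
#' @return Named integer vector.
#' @export
carbon_atom_counts <- function() {
  c(glucose = 6L, fructose = 6L, sucrose = 12L, xylose = 5L,
    glycerol = 3L, ethanol = 2L)
}

#' Fix carbon and nitrogen uptake and install the matching biomass
#'
#' Fixes both bounds of the carbon exchange to the negative uptake rate (the
#' carbon uptake must be realized exactly so the C/N ratio between uptake
#' rates is well defined), offers nitrogen as an uptake capacity (lower bound
#' only: cells cannot be compelled to assimilate excess nitrogen, and in the
#' nitrogen-limited regime that drives lipid accumulation the offered rate is
#' fully consumed anyway), and, in dynamic mode, rebuilds the biomass
#' reaction for the C/N (g/g) implied by those uptake rates.
#'
#' @param model A `gem` with minimal medium applied.
#' @param carbon_exchange,nitrogen_exchange Exchange reaction ids.
#' @param carbon_uptake,nitrogen_uptake Uptake magnitudes (mmol/gDCW/h).
#' @param dynamic_biomass Rebuild the biomass reaction per condition?
#' @param gam Growth-associated maintenance (mmol ATP per g biomass).
#' @param fix_nitrogen Also fix the nitrogen upper bound (force consumption).
#' @return List `model`, `cn` (the [cn_ratio] implied by the uptakes).
#' @export
apply_cn_condition <- function(model, carbon_exchange, nitrogen_exchange,
                               carbon_uptake, nitrogen_uptake,
                               dynamic_biomass = TRUE, gam = 60,
                               fix_nitrogen = FALSE) {
  cn <- if (carbon_uptake > 0) {
    cn_ratio_from_uptakes(model, carbon_exchange, nitrogen_exchange,
                          carbon_uptake, nitrogen_uptake)
  } else {
    cn_ratio(0)  # degenerate no-carbon condition
  }
  model <- set_bounds(model, carbon_exchange, lb = -carbon_uptake,
                      ub = -carbon_uptake)
  model <- set_bounds(model, nitrogen_exchange, lb = -nitrogen_uptake,
                      ub = if (fix_nitrogen) -nitrogen_uptake else 0)
  if (dynamic_biomass) {
    comp <- compose_biomass(cn$mass, mode = "starvation")
    model <- install_biomass(model, comp, gam = gam)
  }
  list(model = model, cn = cn)
}

#' Lipid-production protocol
#'
#' Implements the fixed-biomass lipid maximization: compute the maximal
#' growth rate mu*; if mu* exceeds `mu_max` constrain the biomass flux to
#' `[window * mu_max, mu_max]`, otherwise to `[window * mu*, mu*]`; then
#' maximize the lipid-body exchange. If mu* is below `growth_tol` (or the
#' model is infeasible) the lipid flux is zero with a no-growth flag.
#'
#' @param model A `gem` with the condition (uptakes, biomass) installed.
#' @param lipid_exchange Reaction id of the lipid-body exchange.
#' @param params See [protocol_params()].
#' @param lipid_pool_rxn Reaction id of the total-lipid pool; its flux at the
#'   lipid-maximizing optimum is reported as `lipid_synthesis` (biomass-bound
#'   lipid plus export), the quantity whose C/N response distinguishes the
#'   condition-specific from the static biomass.
#' @return List `mu_star`, `biomass_bounds`, `lipid_flux` (lipid-body export,
#'   mmol/gDCW/h), `lipid_synthesis`, `no_growth`, `solution` (the
#'   lipid-maximizing `flux_solution`, NULL when no growth),
#'   `constrained_model` (with the biomass window applied).
#' @export
lipid_production_protocol <- function(model, lipid_exchange = "EX_lipid_body",
                                      params = protocol_params(),
                                      lipid_pool_rxn = "LIPIDPOOL") {
  if (!lipid_exchange %in% model$rxns$id) {
    stop("lipid exchange not in model: ", lipid_exchange, call. = FALSE)
  }
  growth <- fba(model)
  mu_star <- if (growth$status == "optimal") growth$objective else 0
  if (growth$status != "optimal" || mu_star <= params$growth_tol) {
    return(list(mu_star = mu_star, biomass_bounds = c(0, 0), lipid_flux = 0,
                lipid_synthesis = 0, no_growth = TRUE, solution = NULL,
                constrained_model = model))
  }
  bb <- if (mu_star > params$mu_max) {
    c(params$window * params$mu_max, params$mu_max)
  } else {
    c(params$window * mu_star, mu_star)
  }
  model2 <- set_bounds(model, model$objective, lb = bb[1], ub = bb[2])
  lip <- fba(model2, objective = lipid_exchange, sense = "max",
             basis = growth$basis)
  if (lip$status != "optimal") {
    # numerically brittle window: retreat marginally and retry once
    model2 <- set_bounds(model, model$objective,
                         lb = bb[1] * (1 - 1e-9), ub = bb[2])
    lip <- fba(model2, objective = lipid_exchange, sense = "max")
  }
  ok <- lip$status == "optimal"
  synth <- if (ok && lipid_pool_rxn %in% model$rxns$id) {
    lip$fluxes[[lipid_pool_rxn]]
  } else if (ok) NA_real_ else 0
  list(mu_star = mu_star, biomass_bounds = bb,
       lipid_flux = if (ok) lip$objective else 0,
       lipid_synthesis = synth,
       no_growth = FALSE, solution = lip, constrained_model = model2)
}

#' Simulate gene knockouts
#'
#' Reactions whose gene rule evaluates to FALSE under the deletion lose
#' catalysis (bounds fixed to zero); growth and the lipid protocol are then
#' re-run.
#'
#' @param model A `gem` (condition installed).
#' @param genes Gene ids to delete (may be empty).
#' @param lipid_exchange Lipid-body exchange id (NULL to skip the protocol).
#' @param params See [protocol_params()].
#' @return List `mu`, `lipid_flux`, `disabled` (reaction ids switched off),
#'   `model` (with knockouts applied).
#' @export
knockout_growth <- function(model, genes, lipid_exchange = "EX_lipid_body",
                            params = protocol_params()) {
  genes <- as.character(genes)
  unknown <- setdiff(genes, model$genes)
  if (length(unknown)) {
    stop("unknown gene id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  disabled <- character()
  if (length(genes)) {
    for (i in seq_len(nrow(model$rxns))) {
      tree <- parse_gpr(model$rxns$gpr[i])
      if (is.null(tree)) next
      if (!evaluate_gpr(tree, deleted = genes)) {
        disabled <- c(disabled, model$rxns$id[i])
      }
    }
    if (length(disabled)) model <- set_bounds(model, disabled, lb = 0, ub = 0)
  }
  growth <- fba(model)
  mu <- if (growth$status == "optimal") growth$objective else 0
  lipid <- NA_real_
  if (!is.null(lipid_exchange) && lipid_exchange %in% model$rxns$id) {
    lipid <- lipid_production_protocol(model, lipid_exchange, params)$lipid_flux
  }
  list(mu = mu, lipid_flux = lipid, disabled = disabled, model = model)
}

#' Growth screen over carbon/nitrogen uptake grids
#'
#' For every combination of carbon source, carbon uptake and nitrogen uptake,
#' both exchange bounds are fixed to the tested uptakes, the
#' condition-specific biomass is rebuilt from the uptake-derived C/N (g/g)
#' (dynamic mode), and biomass flux is maximized. Infeasible cells are
#' recorded as zero growth with a flag.
#'
#' @param model A `gem`.
#' @param sources Named character vector mapping source name -> exchange id.
#' @param c_uptakes,n_uptakes Uptake magnitudes to scan (mmol/gDCW/h).
#' @param nitrogen_exchange Nitrogen exchange id.
#' @param equal_cmol Normalize carbon uptakes so every source delivers the
#'   C-mol of the named reference source at the stated uptake.
#' @param reference Reference source name for C-mol normalization.
#' @param dynamic_biomass Rebuild biomass per cell?
#' @param gam Growth-associated maintenance.
#' @return Data frame: source, c_uptake (as applied), n_uptake, cn_gg, mu,
#'   feasible.
#' @export
growth_screen <- function(model, sources, c_uptakes, n_uptakes,
                          nitrogen_exchange = "EX_nh4",
                          equal_cmol = TRUE, reference = "glucose",
                          dynamic_biomass = TRUE, gam = 60) {
  model <- set_minimal_medium(model)
  rows <- list()
  for (src in names(sources)) {
    for (cu in c_uptakes) {
      cu_src <- if (equal_cmol) uptake_for_equal_cmol(src, reference, cu) else cu
      for (nu in n_uptakes) {
        cond <- apply_cn_condition(model, sources[[src]], nitrogen_exchange,
                                   cu_src, nu, dynamic_biomass, gam)
        sol <- fba(cond$model)
        feasible <- sol$status == "optimal"
        rows[[length(rows) + 1L]] <- data.frame(
          source = src, c_uptake = cu_src, n_uptake = nu,
          cn_gg = cond$cn$mass,
          mu = if (feasible) sol$objective else 0,
          feasible = feasible, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
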