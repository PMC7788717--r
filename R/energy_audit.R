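#' @title Energy-generating cycle audit
#' @description Detects thermodynamically infeasible energy-generating
#'   cycles: dissipation reactions for the eight energy carriers are added,
#'   all network fluxes are clamped to unit ranges, every uptake is closed,
#'   and each dissipation reaction is maximized. Any positive maximum
#'   certifies a cycle that produces the carrier from nothing; the reactions
#'   carrying flux at that optimum are the implicated support.
#' @name energy-audit
NULL

dissipation_specs <- function() {
  list(
    atp    = "atp_c + h2o_c -> adp_c + pi_c + h_c",
    ctp    = "ctp_c + h2o_c -> cdp_c + pi_c + h_c",
    gtp    = "gtp_c + h2o_c -> gdp_c + pi_c + h_c",
    utp    = "utp_c + h2o_c -> udp_c + pi_c + h_c",
    nadh   = "nadh_c -> nad_c + h_c",
    nadph  = "nadph_c -> nadp_c + h_c",
    fadh2  = "fadh2_c -> fad_c + 2 h_c",
    proton = "h_c -> h_e")
}

#' Add energy dissipation reactions
#'
#' One irreversible dissipation reaction per carrier (ATP, CTP, GTP, UTP,
#' NADH, NADPH, FADH2 and the transmembrane proton), hydrolyzing or
#' discharging exactly one carrier equivalent in the cytosol. Reactions are
#' flagged pseudo so they never count as metabolic; carriers missing from the
#' model are skipped with a warning, and repeated invocation is idempotent.
#'
#' @param model A `gem`.
#' @return Modified model with reactions `DISS_atp`, ..., `DISS_proton`.
#' @export
add_dissipation_reactions <- function(model) {
  specs <- dissipation_specs()
  for (carrier in names(specs)) {
    id <- paste0("DISS_", carrier)
    if (id %in% model$rxns$id) next
    st <- parse_rxn_equation(specs[[carrier]])
    if (!all(st$met %in% model$mets$id)) {
      warning("dissipation carrier missing, skipped: ", carrier, call. = FALSE)
      next
    }
    model$rxns <- rbind(model$rxns, data.frame(
      id = id, name = paste(carrier, "dissipation"), lb = 0, ub = 1000,
      gpr = NA_character_, subsystem = "energy dissipation", pseudo = TRUE,
      stringsAsFactors = FALSE))
    model$stoich <- rbind(model$stoich, data.frame(
      rxn = id, met = st$met, coef = st$coef, stringsAsFactors = FALSE))
  }
  validate_gem(model)
}

#' Detect infeasible energy-generating cycles
#'
#' All non-dissipation reactions are clamped to `[-1, 1]` (reversible, i.e.
#' negative lower bound) or `[0, 1]` (irreversible); every exchange uptake is
#' closed (`lb = 0`; secretion stays open, it cannot fuel a cycle). Each
#' dissipation reaction is then maximized by FBA. The model passes when all
#' eight maxima are at most `tol`.
#'
#' @param model A `gem`; dissipation reactions are added if absent.
#' @param tol Pass threshold on each maximal dissipation flux.
#' @return Object of class `audit_report`: data frame `maxima` (carrier,
#'   max_flux, pass), list `supports` (reaction ids with `|v| > tol` at each
#'   positive optimum), logical `pass`.
#' @export
detect_energy_cycles <- function(model, tol = 1e-6) {
  model <- add_dissipation_reactions(model)
  diss <- model$rxns$id[startsWith(model$rxns$id, "DISS_")]
  other <- setdiff(model$rxns$id, diss)
  idx <- match(other, model$rxns$id)
  reversible <- model$rxns$lb[idx] < 0
  # clamp to the unit range: forced positive lower bounds (maintenance) are
  # relaxed to 0, and knocked-out reactions (ub <= 0) stay off
  model <- set_bounds(model, other, lb = ifelse(reversible, -1, 0),
                      ub = pmin(model$rxns$ub[idx], 1))
  model <- set_bounds(model, exchange_reactions(model), lb = 0)
  maxima <- data.frame(carrier = sub("^DISS_", "", diss), rxn = diss,
                       max_flux = NA_real_, stringsAsFactors = FALSE)
  supports <- list()
  for (i in seq_along(diss)) {
    sol <- fba(model, objective = diss[i], sense = "max")
    maxima$max_flux[i] <- if (sol$status == "optimal") sol$objective else 0
    supports[[maxima$carrier[i]]] <- if (maxima$max_flux[i] > tol) {
      setdiff(names(sol$fluxes)[abs(sol$fluxes) > tol], diss[i])
    } else character()
  }
  maxima$pass <- maxima$max_flux <= tol
  structure(list(maxima = maxima, supports = supports,
                 pass = all(maxima$pass), tol = tol),
            class = "audit_report")
}

#' @export
print.audit_report <- function(x, ...) {
  cat(sprintf("<audit_report> %s\n", if (x$pass) "PASS: no energy-generating cycles"
              else "FAIL: energy-generating cycle(s) detected"))
  for (i in seq_len(nrow(x$maxima))) {
    cat(sprintf("  %-7s max dissipation %.3g%s\n", x$maxima$carrier[i],
                x$maxima$max_flux[i],
                if (!x$maxima$pass[i]) paste0("  support: ",
                  paste(x$supports[[x$maxima$carrier[i]]], collapse = " "))
                else ""))
  }
  invisible(x)
}
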