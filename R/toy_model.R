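#' @title Synthetic oleaginous-yeast model
#' @description Builds a small compartmentalized genome-scale model that
#'   mirrors the lipid-synthesis topology of an oleaginous yeast: glycolysis,
#'   oxidative and non-oxidative pentose phosphate pathway, the
#'   phosphoketolase route for xylose, a mitochondrial TCA cycle with citrate
#'   export, ATP-citrate lyase (ACL) as the sole cytosolic acetyl-CoA source,
#'   acetyl-CoA carboxylase, a lumped fatty acid synthase, elongation and
#'   desaturation to the C18 acyl-CoAs, the artificial acyl-CoA pool, TAG and
#'   phospholipid synthesis, a lipid pseudo-metabolite exported through a
#'   lipid-body exchange, and lumped macromolecule synthesis feeding a
#'   condition-specific biomass reaction. The model is the test bed for the
#'   whole analysis pipeline and ships with a manifest of ground-truth
#'   properties.
#' @name toy-model
NULL

toy_formulas <- c(
  glc__D = "C6H12O6", fru = "C6H12O6", sucr = "C12H22O11", xyl__D = "C5H10O5",
  glyc = "C3H8O3", etoh = "C2H6O", ac = "C2H3O2", acald = "C2H4O",
  actp = "C2H3O5P", o2 = "O2", co2 = "CO2", h2o = "H2O", h = "H",
  pi = "HO4P", ppi = "HO7P2", so4 = "O4S", nh4 = "H4N", urea = "CH4N2O",
  fe2 = "Fe", k = "K", na1 = "Na",
  g6p = "C6H11O9P", f6p = "C6H11O9P", fdp = "C6H10O12P2", dhap = "C3H5O6P",
  g3p = "C3H5O6P", `13dpg` = "C3H4O10P2", `3pg` = "C3H4O7P", `2pg` = "C3H4O7P",
  pep = "C3H2O6P", pyr = "C3H3O3",
  `6pgl` = "C6H9O9P", `6pgc` = "C6H10O10P", ru5p__D = "C5H9O8P",
  xu5p__D = "C5H9O8P", r5p = "C5H9O8P", s7p = "C7H13O10P", e4p = "C4H7O7P",
  xylt = "C5H12O5", xylu__D = "C5H10O5", glyc3p = "C3H7O6P",
  atp = "C10H12N5O13P3", adp = "C10H12N5O10P2", amp = "C10H12N5O7P",
  nad = "C21H26N7O14P2", nadh = "C21H27N7O14P2",
  nadp = "C21H25N7O17P3", nadph = "C21H26N7O17P3",
  fad = "C27H31N9O15P2", fadh2 = "C27H33N9O15P2",
  coa = "C21H32N7O16P3S", accoa = "C23H34N7O17P3S", malcoa = "C24H33N7O19P3S",
  cit = "C6H5O7", icit = "C6H5O7", akg = "C5H4O5",
  succoa = "C25H35N7O19P3S", succ = "C4H4O4", fum = "C4H2O4",
  mal__L = "C4H4O5", oaa = "C4H2O5",
  glu__L = "C5H8NO4", ser__L = "C3H7NO3", asp__L = "C4H6NO4",
  ctp = "C9H12N3O14P3", cdp = "C9H12N3O11P2", cmp = "C9H12N3O8P",
  gtp = "C10H12N5O14P3", gdp = "C10H12N5O11P2",
  utp = "C9H11N2O15P3", udp = "C9H11N2O12P2",
  pmtcoa = "C37H62N7O17P3S", stcoa = "C39H66N7O17P3S",
  odecoa = "C39H64N7O17P3S", lnlccoa = "C39H62N7O17P3S")

toy_met_names <- c(
  glc__D = "D-glucose", fru = "D-fructose", sucr = "sucrose",
  xyl__D = "D-xylose", glyc = "glycerol", etoh = "ethanol", ac = "acetate",
  acald = "acetaldehyde", actp = "acetyl phosphate", o2 = "oxygen",
  co2 = "carbon dioxide", h2o = "water", h = "proton", pi = "phosphate",
  ppi = "diphosphate", so4 = "sulphate", nh4 = "ammonium", urea = "urea",
  fe2 = "iron(II)", k = "potassium", na1 = "sodium")

#' Parse a reaction equation string
#'
#' `"a + 2 b -> c"` is irreversible, `"a <-> b"` reversible. Species on both
#' sides are merged by summed signed coefficients.
#' @keywords internal
parse_rxn_equation <- function(eq) {
  rev <- grepl("<->", eq, fixed = TRUE)
  sides <- strsplit(eq, if (rev) "<->" else "->", fixed = TRUE)[[1]]
  if (length(sides) == 1L) sides <- c(sides, "")
  term <- function(side, sign) {
    side <- trimws(side)
    if (!nzchar(side)) return(NULL)
    parts <- trimws(strsplit(side, " + ", fixed = TRUE)[[1]])
    out <- lapply(parts, function(p) {
      m <- regmatches(p, regexec("^([0-9.]+ )?(\\S+)$", p))[[1]]
      if (length(m) != 3L) stop("bad term: ", p, call. = FALSE)
      coef <- if (nzchar(trimws(m[2]))) as.numeric(trimws(m[2])) else 1
      data.frame(met = m[3], coef = sign * coef, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  }
  st <- rbind(term(sides[1], -1), term(sides[2], +1))
  st <- stats::aggregate(coef ~ met, st, sum)
  st <- st[st$coef != 0, , drop = FALSE]
  attr(st, "reversible") <- rev
  st
}

#' Build the synthetic oleaginous-yeast model
#'
#' The default build reproduces the study conditions: no ethanol
#' assimilation pathway (so ethanol supports no growth), no cytosolic
#' acetyl-CoA synthetase bypass (so ACL is essential for lipid synthesis and
#' hence growth), glycerol import lumped with its proton-pump ATP cost, the
#' FAD-linked glycerol-3-phosphate shuttle lumped with zero phosphorylation
#' yield, non-growth maintenance fixed at 1 mmol ATP/gDCW/h, the minimal
#' medium opened, and glucose at the validation uptake of 10 mmol/gDCW/h with
#' the static nitrogen-replete biomass installed.
#'
#' @param include_ethanol_assimilation Add alcohol/aldehyde dehydrogenase and
#'   acetyl-CoA synthetase so ethanol becomes a usable carbon source (this
#'   also creates an ACL bypass, as in non-oleaginous yeasts).
#' @param gam Growth-associated maintenance, mmol ATP per g biomass.
#' @param ngam Non-growth-associated maintenance flux (both bounds).
#' @param seed,bound_jitter Optional: multiply the default 1000-cap upper
#'   bounds of metabolic reactions by `1 + U(-j, j)` noise for robustness
#'   property tests. The construction is otherwise fully deterministic.
#' @return List with elements `model` (a [new_gem()] object) and `manifest`
#'   (ground truth: category counts, lumped reactions, essential genes,
#'   carbon sources, pathway map, tracked reaction ids).
#' @export
build_toy_gem <- function(include_ethanol_assimilation = FALSE,
                          gam = 60, ngam = 1, seed = NULL, bound_jitter = 0) {
  mets <- list(); rxns <- list(); stoich <- list(); intended <- character()

  add_met <- function(base, cmp, mw = NA_real_, name = NULL) {
    id <- paste0(base, "_", cmp)
    formula <- if (base %in% names(toy_formulas)) toy_formulas[[base]] else NA_character_
    if (is.na(mw) && !is.na(formula)) mw <- molecular_weight(formula)
    nm <- if (!is.null(name)) name else
      if (base %in% names(toy_met_names)) toy_met_names[[base]] else base
    mets[[id]] <<- data.frame(id = id, name = nm, compartment = cmp,
                              formula = formula, mw = mw,
                              stringsAsFactors = FALSE)
    id
  }
  add_rxn <- function(id, eq, name = id, gpr = NA_character_,
                      subsystem = NA_character_, lb = NULL, ub = NULL,
                      pseudo = FALSE, category = "metabolic") {
    st <- parse_rxn_equation(eq)
    if (is.null(lb)) lb <- if (attr(st, "reversible")) -1000 else 0
    if (is.null(ub)) ub <- 1000
    rxns[[id]] <<- data.frame(id = id, name = name, lb = lb, ub = ub,
                              gpr = gpr, subsystem = subsystem,
                              pseudo = pseudo, stringsAsFactors = FALSE)
    stoich[[id]] <<- data.frame(rxn = id, met = st$met, coef = st$coef,
                                stringsAsFactors = FALSE)
    intended[[id]] <<- category
    id
  }

  # ---- metabolites ---------------------------------------------------------
  for (b in c("glc__D", "fru", "sucr", "xyl__D", "glyc", "etoh", "ac", "o2",
              "co2", "h2o", "h", "pi", "so4", "nh4", "urea", "fe2", "k", "na1"))
    add_met(b, "e")
  for (b in c("glc__D", "fru", "sucr", "xyl__D", "glyc", "etoh", "ac", "actp",
              "o2", "co2", "h2o", "h", "pi", "ppi", "so4", "nh4", "urea",
              "fe2", "k", "na1",
              "g6p", "f6p", "fdp", "dhap", "g3p", "13dpg", "3pg", "2pg",
              "pep", "pyr", "6pgl", "6pgc", "ru5p__D", "xu5p__D", "r5p",
              "s7p", "e4p", "xylt", "xylu__D", "glyc3p",
              "atp", "adp", "nad", "nadh", "nadp", "nadph", "fad", "fadh2",
              "coa", "accoa", "malcoa", "cit", "oaa", "mal__L", "akg",
              "glu__L", "ser__L", "asp__L",
              "ctp", "cdp", "cmp", "gtp", "gdp", "utp", "udp",
              "pmtcoa", "stcoa", "odecoa", "lnlccoa"))
    add_met(b, "c")
  for (b in c("pyr", "accoa", "coa", "cit", "icit", "akg", "succoa", "succ",
              "fum", "mal__L", "oaa", "nad", "nadh", "fad", "fadh2",
              "atp", "adp", "pi", "h", "h2o", "co2", "o2"))
    add_met(b, "m")

  # averaged lipid species: no elemental formula, molecular weights derived
  # chain-wise so every lipid reaction conserves mass exactly
  mw <- function(f) molecular_weight(f)
  pool <- acyl_pool_reaction()
  acyl_mw <- c(mw("C37H62N7O17P3S"), mw("C39H66N7O17P3S"),
               mw("C39H64N7O17P3S"), mw("C39H62N7O17P3S"))
  mw_pool <- sum(pool$coef * acyl_mw)
  mw_coa <- mw("C21H32N7O16P3S")
  # one pool unit carries sum(coef) mmol of CoA moiety, released on acylation
  coa_per_pool <- sum(pool$coef)
  acyl_transfer <- mw_pool - coa_per_pool * mw_coa  # mass moved per acylation
  mw_pa <- mw("C3H7O6P") + 2 * acyl_transfer
  mw_dag <- mw_pa + mw("H2O") - mw("HO4P")
  mw_tag <- mw_dag + acyl_transfer
  mw_cdpdag <- mw_pa + mw("C9H12N3O14P3") + mw("H") - mw("HO7P2")
  mw_ps <- mw_cdpdag + mw("C3H7NO3") - mw("C9H12N3O8P") - mw("H")
  mw_pe <- mw_ps + mw("H") - mw("CO2")
  mw_pc <- mw_pe + 3 * (mw("C") + 2 * mw("H"))  # three lumped methylations

  add_met("acylpool", "c", mw = mw_pool, name = "acyl-CoA pool (averaged)")
  add_met("pa", "c", mw = mw_pa, name = "phosphatidate (averaged)")
  add_met("dag", "c", mw = mw_dag, name = "diacylglycerol (averaged)")
  add_met("tag", "c", mw = mw_tag, name = "triacylglycerol (averaged)")
  add_met("cdpdag", "c", mw = mw_cdpdag, name = "CDP-diacylglycerol (averaged)")
  add_met("ps", "c", mw = mw_ps, name = "phosphatidylserine (averaged)")
  add_met("pe", "c", mw = mw_pe, name = "phosphatidylethanolamine (averaged)")
  add_met("pc", "c", mw = mw_pc, name = "phosphatidylcholine (averaged)")
  mw_carb <- mw("C6H11O9P") - mw("HO4P")       # anhydroglucose residue
  add_met("carb", "c", mw = mw_carb, name = "carbohydrate (biomass pseudo)")
  add_met("prot", "c", mw = 110, name = "protein (biomass pseudo, avg residue)")
  add_met("other", "c", mw = 300, name = "nucleic acids/cofactors/minerals (pseudo)")
  add_met("lipid", "c", mw = 1000, name = "total lipid (standardized pseudo)")
  add_met("lipid", "l", mw = 1000, name = "total lipid (lipid body)")
  add_met("lipid", "e", mw = 1000, name = "total lipid (exported)")
  add_met("biomass", "c", mw = 1000, name = "biomass (standardized pseudo)")

  # ---- exchanges (positive flux = secretion) -------------------------------
  for (b in c("glc__D", "fru", "sucr", "xyl__D", "glyc", "etoh", "ac", "o2",
              "co2", "h2o", "h", "pi", "so4", "nh4", "urea", "fe2", "k", "na1"))
    add_rxn(paste0("EX_", sub("__D$", "", b)), paste0(b, "_e ->"),
            name = paste("exchange of", b), lb = 0, ub = 1000,
            subsystem = "exchange", category = "exchange")
  add_rxn("EX_lipid_body", "lipid_e ->", name = "lipid body exchange",
          lb = 0, ub = 1000, subsystem = "exchange", category = "exchange")

  # ---- transport -----------------------------------------------------------
  tr <- function(id, eq, gpr = NA, nm = id)
    add_rxn(id, eq, name = nm, gpr = gpr, subsystem = "transport",
            category = "transport")
  tr("GLCt", "glc__D_e -> glc__D_c", "gHXT1")
  tr("FRUt", "fru_e -> fru_c", "gHXT1")
  tr("SUCRt", "sucr_e -> sucr_c", "gMAL11")
  tr("XYLt", "xyl__D_e -> xyl__D_c", "gHXT2")
  # glycerol proton symport lumped with its plasma-membrane ATPase cost
  tr("GLYCt", "glyc_e + atp_c + h2o_c -> glyc_c + adp_c + pi_c + h_c", "gSTL1")
  tr("ETOHt", "etoh_e <-> etoh_c")
  tr("ACt", "ac_c -> ac_e")
  tr("O2t", "o2_e <-> o2_c")
  tr("CO2t", "co2_c <-> co2_e")
  tr("H2Ot", "h2o_c <-> h2o_e")
  tr("PIt", "pi_e <-> pi_c", "gPHO84")
  tr("SO4t", "so4_e <-> so4_c")
  tr("NH4t", "nh4_e <-> nh4_c", "gMEP1")
  tr("UREAt", "urea_e <-> urea_c", "gDUR3")
  tr("FE2t", "fe2_e <-> fe2_c")
  tr("Kt", "k_e <-> k_c")
  tr("NAt", "na1_e <-> na1_c")
  tr("PMA1", "atp_c + h2o_c -> adp_c + pi_c + h_e", "gPMA1",
     nm = "plasma membrane proton pump (lumped)")
  tr("O2tm", "o2_c <-> o2_m")
  tr("CO2tm", "co2_m <-> co2_c")
  tr("H2Otm", "h2o_c <-> h2o_m")
  tr("PItm", "pi_c <-> pi_m", "gMIR1")
  tr("Htm", "h_c <-> h_m")
  tr("ANT", "atp_m + adp_c -> atp_c + adp_m", "gAAC1",
     nm = "ADP/ATP antiporter")
  tr("PYRtm", "pyr_c <-> pyr_m", "gMPC1")
  tr("CITtcm", "cit_m <-> cit_c", "gCTP1",
     nm = "citrate transport, mitochondria to cytosol")
  tr("MALtcm", "mal__L_c <-> mal__L_m", "gDIC1")
  tr("AKGtcm", "akg_m <-> akg_c", "gODC1")
  tr("LIPIDt_cl", "lipid_c -> lipid_l", nm = "lipid deposition into lipid body")
  tr("LIPIDt_le", "lipid_l -> lipid_e", nm = "lipid body export")

  # ---- glycolysis ----------------------------------------------------------
  gly <- function(id, eq, gpr, nm = id)
    add_rxn(id, eq, name = nm, gpr = gpr, subsystem = "glycolysis")
  gly("HEX1", "glc__D_c + atp_c -> g6p_c + adp_c + h_c", "gHXK1 or gGLK1")
  gly("HEX2", "fru_c + atp_c -> f6p_c + adp_c + h_c", "gHXK1")
  gly("SUCRinv", "sucr_c + h2o_c -> glc__D_c + fru_c", "gSUC2")
  gly("PGI", "g6p_c <-> f6p_c", "gPGI1")
  gly("PFK", "f6p_c + atp_c -> fdp_c + adp_c + h_c", "gPFK1 and gPFK2")
  gly("FBA", "fdp_c <-> dhap_c + g3p_c", "gFBA1")
  gly("FBP", "fdp_c + h2o_c -> f6p_c + pi_c", "gFBP1")  # gluconeogenesis
  gly("TPI", "dhap_c <-> g3p_c", "gTPI1")
  gly("GAPD", "g3p_c + nad_c + pi_c <-> 13dpg_c + nadh_c + h_c", "gTDH1")
  gly("PGK", "13dpg_c + adp_c <-> 3pg_c + atp_c", "gPGK1")
  gly("PGM", "3pg_c <-> 2pg_c", "gGPM1")
  gly("ENO", "2pg_c <-> pep_c + h2o_c", "gENO1")
  gly("PYK", "pep_c + adp_c + h_c -> pyr_c + atp_c", "gPYK1")

  # ---- pentose phosphate pathway ------------------------------------------
  ppp <- function(id, eq, gpr)
    add_rxn(id, eq, gpr = gpr, subsystem = "pentose phosphate pathway")
  ppp("G6PDH2r", "g6p_c + nadp_c -> 6pgl_c + nadph_c + h_c", "gZWF1")
  ppp("PGL", "6pgl_c + h2o_c -> 6pgc_c + h_c", "gSOL3")
  ppp("GND", "6pgc_c + nadp_c -> ru5p__D_c + co2_c + nadph_c", "gGND1")
  ppp("RPI", "ru5p__D_c <-> r5p_c", "gRKI1")
  ppp("RPE", "ru5p__D_c <-> xu5p__D_c", "gRPE1")
  ppp("TKT1", "xu5p__D_c + r5p_c <-> g3p_c + s7p_c", "gTKL1")
  ppp("TALA", "g3p_c + s7p_c <-> e4p_c + f6p_c", "gTAL1")
  ppp("TKT2", "xu5p__D_c + e4p_c <-> g3p_c + f6p_c", "gTKL1")

  # ---- xylose assimilation and phosphoketolase -----------------------------
  xyl <- function(id, eq, gpr, sub = "xylose assimilation")
    add_rxn(id, eq, gpr = gpr, subsystem = sub)
  xyl("XYLR", "xyl__D_c + nadph_c + h_c -> xylt_c + nadp_c", "gXYL1")
  xyl("XYLDH", "xylt_c + nad_c -> xylu__D_c + nadh_c + h_c", "gXYL2")
  xyl("XYLK", "xylu__D_c + atp_c -> xu5p__D_c + adp_c + h_c", "gXKS1")
  xyl("PKETX", "xu5p__D_c + pi_c -> actp_c + g3p_c + h2o_c", "gXPK1",
      sub = "phosphoketolase")
  xyl("ACTPH", "actp_c + h2o_c -> ac_c + pi_c + h_c", NA,
      sub = "phosphoketolase")

  # ---- glycerol ------------------------------------------------------------
  add_rxn("GLYK", "glyc_c + atp_c -> glyc3p_c + adp_c + h_c",
          gpr = "gGUT1a or gGUT1b", subsystem = "glycerol metabolism")
  # FAD-linked G3P dehydrogenase lumped with non-phosphorylating oxidation
  add_rxn("G3PDfad", "glyc3p_c + fad_c -> dhap_c + fadh2_c",
          gpr = "gGUT2", subsystem = "glycerol metabolism")
  add_rxn("GPDanab", "dhap_c + nadh_c + h_c -> glyc3p_c + nad_c",
          gpr = "gGPD1 or gGPD2", subsystem = "glycerol metabolism")

  # ---- TCA cycle and anaplerosis (mitochondrial) ---------------------------
  tca <- function(id, eq, gpr)
    add_rxn(id, eq, gpr = gpr, subsystem = "TCA cycle")
  tca("PDHm", "pyr_m + coa_m + nad_m -> accoa_m + co2_m + nadh_m",
      "gPDA1 and gPDB1")
  tca("PCm", "pyr_m + co2_m + atp_m + h2o_m -> oaa_m + adp_m + pi_m + 2 h_m",
      "gPYC1")
  tca("CSm", "accoa_m + oaa_m + h2o_m -> cit_m + coa_m + h_m", "gCIT1")
  tca("ACONTm", "cit_m <-> icit_m", "gACO1")
  tca("ICDHxm", "icit_m + nad_m -> akg_m + co2_m + nadh_m", "gIDH1")
  tca("AKGDm", "akg_m + coa_m + nad_m -> succoa_m + co2_m + nadh_m",
      "gKGD1 and gKGD2")
  tca("SUCOASm", "succoa_m + adp_m + pi_m <-> succ_m + coa_m + atp_m", "gLSC1")
  tca("SUCDm", "succ_m + fad_m -> fum_m + fadh2_m", "gSDH1 and gSDH2")
  tca("FUMm", "fum_m + h2o_m <-> mal__L_m", "gFUM1")
  tca("MDHm", "mal__L_m + nad_m <-> oaa_m + nadh_m + h_m", "gMDH1")

  # ---- cytosolic carbon / redox -------------------------------------------
  add_rxn("MDHc", "mal__L_c + nad_c <-> oaa_c + nadh_c + h_c", gpr = "gMDH2",
          subsystem = "cytosolic carbon metabolism")
  # NAD-dependent, mitochondrial (as in the organism): regenerates pyruvate
  # but is not a cytosolic NADPH source - that burden falls on the PPP
  tca("MEm", "mal__L_m + nad_m -> pyr_m + co2_m + nadh_m", "gMAE1")
  add_rxn("AAT", "oaa_c + glu__L_c <-> asp__L_c + akg_c", gpr = "gAAT1",
          subsystem = "amino acid lump")

  # ---- oxidative phosphorylation (lumped) ----------------------------------
  # P/O: mitochondrial NADH 2, mitochondrial FADH2 1.2, external (cytosolic)
  # NADH 1, cytosolic FADH2 (glycerol-phosphate shuttle) 0
  add_rxn("NADHOXm",
          "nadh_m + 3 h_m + 0.5 o2_m + 2 adp_m + 2 pi_m -> nad_m + 3 h2o_m + 2 atp_m",
          gpr = "gNDI1", subsystem = "oxidative phosphorylation")
  add_rxn("FADH2OXm",
          "fadh2_m + 0.5 o2_m + 1.2 adp_m + 1.2 pi_m + 1.2 h_m -> fad_m + 2.2 h2o_m + 1.2 atp_m",
          subsystem = "oxidative phosphorylation")
  add_rxn("NADHOXc",
          "nadh_c + 2 h_c + 0.5 o2_c + adp_c + pi_c -> nad_c + 2 h2o_c + atp_c",
          gpr = "gNDE1", subsystem = "oxidative phosphorylation")
  add_rxn("FADH2OXc", "fadh2_c + 0.5 o2_c -> fad_c + h2o_c",
          subsystem = "oxidative phosphorylation")

  # ---- nitrogen assimilation and amino-acid lump ---------------------------
  add_rxn("GDH", "akg_c + nh4_c + nadph_c + h_c -> glu__L_c + h2o_c + nadp_c",
          gpr = "gGDH1", subsystem = "amino acid lump")
  add_rxn("UREASE", "urea_c + h2o_c + 2 h_c -> co2_c + 2 nh4_c",
          gpr = "gDUR1", subsystem = "amino acid lump")
  add_rxn("SERSYN",
          "3pg_c + nad_c + glu__L_c + h2o_c -> ser__L_c + akg_c + pi_c + nadh_c + h_c",
          gpr = "gSER1 and gSER2", subsystem = "amino acid lump",
          name = "serine synthesis (lumped three-step branch)")

  # ---- fatty acid synthesis ------------------------------------------------
  lip <- function(id, eq, gpr, nm = id)
    add_rxn(id, eq, name = nm, gpr = gpr, subsystem = "lipid synthesis")
  lip("ACL", "cit_c + atp_c + coa_c -> accoa_c + oaa_c + adp_c + pi_c",
      "gACL1", nm = "ATP-citrate lyase")
  lip("ACC", "accoa_c + co2_c + atp_c + h2o_c -> malcoa_c + adp_c + pi_c + 2 h_c",
      "gACC1", nm = "acetyl-CoA carboxylase")
  lip("FAS",
      "accoa_c + 7 malcoa_c + 14 nadph_c + 21 h_c -> pmtcoa_c + 14 nadp_c + 7 coa_c + 7 co2_c + 7 h2o_c",
      "gFAS1 and gFAS2", nm = "fatty acid synthase (lumped)")
  lip("ELO18", "pmtcoa_c + malcoa_c + 2 nadph_c + 3 h_c -> stcoa_c + 2 nadp_c + co2_c + coa_c + h2o_c",
      "gELO1", nm = "C16 to C18 elongation")
  lip("DESAT18_1", "stcoa_c + nadh_c + h_c + o2_c -> odecoa_c + nad_c + 2 h2o_c",
      "gOLE1", nm = "delta-9 desaturase")
  lip("DESAT18_2", "odecoa_c + nadh_c + h_c + o2_c -> lnlccoa_c + nad_c + 2 h2o_c",
      "gFAD2", nm = "delta-12 desaturase")
  add_rxn("ACYLPOOL",
          paste0(sprintf("%.6g %s", pool$coef, pool$met), collapse = " + ") %+%
            " -> acylpool_c",
          name = "acyl-CoA pool (artificial)", subsystem = "lipid synthesis",
          pseudo = TRUE, category = "pseudo")

  # ---- TAG and phospholipid synthesis --------------------------------------
  lip("GPAT_LP",
      sprintf("glyc3p_c + 2 acylpool_c -> pa_c + %.8g coa_c", 2 * coa_per_pool),
      "gGPT1 and gSLC1", nm = "G3P acylation to phosphatidate (lumped)")
  lip("PAP", "pa_c + h2o_c -> dag_c + pi_c", "gPAH1")
  lip("DGAT",
      sprintf("dag_c + acylpool_c -> tag_c + %.8g coa_c", coa_per_pool),
      "gDGA1 or gLRO1")
  lip("CDS", "pa_c + ctp_c + h_c -> cdpdag_c + ppi_c", "gCDS1")
  add_rxn("PPA", "ppi_c + h2o_c -> 2 pi_c + h_c", gpr = "gIPP1",
          subsystem = "cytosolic carbon metabolism")
  lip("PSS", "cdpdag_c + ser__L_c -> ps_c + cmp_c + h_c", "gCHO1")
  lip("PSD", "ps_c + h_c -> pe_c + co2_c", "gPSD1")
  lip("PEMT", "pe_c -> pc_c", "gCHO2",
      nm = "PE methylation to PC (lumped, methyl donor implicit)")
  add_rxn("LIPIDPOOL",
          sprintf("%.15g tag_c + %.15g ps_c + %.15g pe_c + %.15g pc_c -> lipid_c",
                  900 / mw_tag, (100 / 3) / mw_ps, (100 / 3) / mw_pe,
                  (100 / 3) / mw_pc),
          name = "total lipid pool (90% TAG, phospholipids in equal thirds)",
          subsystem = "lipid synthesis", pseudo = TRUE, category = "pseudo")

  # ---- nucleotides ---------------------------------------------------------
  nuc <- function(id, eq, gpr)
    add_rxn(id, eq, gpr = gpr, subsystem = "nucleotide metabolism")
  nuc("CYTK", "atp_c + cmp_c <-> adp_c + cdp_c", "gCMK1")
  nuc("NDKC", "atp_c + cdp_c <-> adp_c + ctp_c", "gYNK1")
  nuc("NDKG", "atp_c + gdp_c <-> adp_c + gtp_c", "gYNK1")
  nuc("NDKU", "atp_c + udp_c <-> adp_c + utp_c", "gYNK1")
  add_rxn("PYRSYN",
          "r5p_c + asp__L_c + nh4_c + 4 atp_c + h2o_c -> ctp_c + 4 adp_c + 4 pi_c + 5 h_c",
          gpr = "gURA2", subsystem = "nucleotide metabolism",
          name = "de novo pyrimidine synthesis (lumped)")

  # ---- macromolecule lumps and biomass -------------------------------------
  add_rxn("CARBSYN", "g6p_c + atp_c + h2o_c -> carb_c + adp_c + 2 pi_c + h_c",
          gpr = "gUGP1", subsystem = "macromolecule synthesis",
          name = "storage/structural carbohydrate synthesis (lumped)")
  add_rxn("PROTSYN",
          "glu__L_c + 4 atp_c + 3 h2o_c -> prot_c + 4 adp_c + 4 pi_c + 4 h_c",
          subsystem = "macromolecule synthesis",
          name = "protein synthesis (lumped, average residue)")
  add_rxn("OTHERSYN",
          "r5p_c + 2 atp_c + 0.01 so4_c + 0.01 fe2_c + 0.01 k_c + 0.01 na1_c + h2o_c -> other_c + 2 adp_c + 2 pi_c + 2 h_c",
          subsystem = "macromolecule synthesis",
          name = "nucleic acid/cofactor/mineral fraction (lumped)")
  add_rxn("ATPM", "atp_c + h2o_c -> adp_c + pi_c + h_c",
          subsystem = "maintenance", lb = ngam, ub = ngam,
          name = "non-growth-associated maintenance")
  add_rxn("BIOMASS", "biomass_c ->", name = "biomass synthesis (installed)",
          subsystem = "biomass", pseudo = TRUE, category = "biomass")
  add_rxn("DM_biomass", "biomass_c ->", name = "biomass drain",
          pseudo = TRUE, subsystem = "biomass", category = "pseudo")

  if (include_ethanol_assimilation) {
    # alcohol/aldehyde dehydrogenase + acetyl-CoA synthetase, plus the
    # glyoxylate shunt and PEP carboxykinase needed to grow on a C2 source
    add_met("acald", "c")
    add_met("amp", "c")
    add_met("icit", "c")
    add_met("glx", "c", name = "glyoxylate")
    mets[["glx_c"]]$formula <- "C2HO3"
    mets[["glx_c"]]$mw <- molecular_weight("C2HO3")
    add_met("succ", "c")
    add_rxn("ADH", "etoh_c + nad_c <-> acald_c + nadh_c + h_c", gpr = "gADH1",
            subsystem = "ethanol assimilation")
    add_rxn("ALDD", "acald_c + nad_c + h2o_c -> ac_c + nadh_c + 2 h_c",
            gpr = "gALD1", subsystem = "ethanol assimilation")
    add_rxn("ACS", "ac_c + atp_c + coa_c -> accoa_c + amp_c + ppi_c",
            gpr = "gACS2", subsystem = "ethanol assimilation")
    add_rxn("ADK1", "amp_c + atp_c <-> 2 adp_c", gpr = "gADK1",
            subsystem = "nucleotide metabolism")
    add_rxn("CSc", "accoa_c + oaa_c + h2o_c -> cit_c + coa_c + h_c",
            gpr = "gCIT2", subsystem = "ethanol assimilation")
    add_rxn("ACONTc", "cit_c <-> icit_c", gpr = "gACO1",
            subsystem = "ethanol assimilation")
    add_rxn("ICL", "icit_c -> glx_c + succ_c", gpr = "gICL1",
            subsystem = "ethanol assimilation")
    add_rxn("MALS", "accoa_c + glx_c + h2o_c -> mal__L_c + coa_c + h_c",
            gpr = "gMLS1", subsystem = "ethanol assimilation")
    add_rxn("PCK", "oaa_c + atp_c -> pep_c + co2_c + adp_c", gpr = "gPCK1",
            subsystem = "ethanol assimilation")
    tr("SUCCtm", "succ_c <-> succ_m", "gSFC1")
  }

  mets <- do.call(rbind, mets)
  rxns <- do.call(rbind, rxns)
  stoich <- do.call(rbind, stoich)
  rownames(mets) <- rownames(rxns) <- rownames(stoich) <- NULL

  if (bound_jitter > 0) {
    if (!is.null(seed)) set.seed(seed)
    cap <- rxns$ub == 1000 & intended[rxns$id] == "metabolic"
    rxns$ub[cap] <- 1000 * (1 + stats::runif(sum(cap), -bound_jitter, bound_jitter))
  }

  model <- new_gem(
    id = "toyGEM_oleaginosus",
    compartments = c(c = "cytosol", e = "extracellular",
                     m = "mitochondrion", l = "lipid particle"),
    mets = mets, rxns = rxns, stoich = stoich,
    genes = sort(unique(unlist(lapply(rxns$gpr, function(g)
      gpr_genes(parse_gpr(g)))))),
    objective = "BIOMASS")

  # validation condition: minimal medium, glucose at -10, replete biomass
  model <- install_biomass(model, compose_biomass(0, mode = "replete"),
                           gam = gam)
  model <- set_minimal_medium(model)
  model <- set_bounds(model, "EX_glc", lb = -protocol_params()$validation_uptake)

  lev <- c("exchange", "transport", "metabolic", "biomass", "pseudo")
  counts <- table(factor(unname(intended[model$rxns$id]), levels = lev))
  manifest <- list(
    category_counts = setNames(as.integer(counts), lev),
    lumped_reactions = c("GPAT_LP", "PAP", "DGAT", "CDS", "PSS", "PSD", "PEMT",
                         "PYRSYN", "CARBSYN", "PROTSYN", "OTHERSYN",
                         "ACYLPOOL", "LIPIDPOOL"),
    essential_genes = c("gACL1", "gACC1", "gFAS1", "gFAS2", "gELO1", "gOLE1",
                        "gFAD2", "gPAH1", "gCDS1", "gCHO1", "gPSD1", "gCHO2",
                        "gCMK1", "gURA2"),
    acl_gene = "gACL1",
    carbon_sources = data.frame(
      name = names(carbon_atom_counts()),
      exchange = c("EX_glc", "EX_fru", "EX_sucr", "EX_xyl", "EX_glyc", "EX_etoh"),
      atoms = as.integer(carbon_atom_counts()),
      stringsAsFactors = FALSE),
    pathways = split(model$rxns$id, model$rxns$subsystem),
    tracked = c(citrate_transport = "CITtcm", acl = "ACL",
                acyl_pool = "ACYLPOOL", lipid_exchange = "EX_lipid_body"),
    lipid_mw = c(acylpool = mw_pool, pa = mw_pa, dag = mw_dag, tag = mw_tag,
                 cdpdag = mw_cdpdag, ps = mw_ps, pe = mw_pe, pc = mw_pc),
    gam = gam, ngam = ngam)

  list(model = model, manifest = manifest)
}

#' String concatenation helper
#' @keywords internal
`%+%` <- function(a, b) paste0(a, b)
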