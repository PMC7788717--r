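#' Construct a genome-scale metabolic model object
#'
#' The `gem` class is a plain-list container for a compartmentalized
#' constraint-based model: a metabolite table, a reaction table, a triplet
#' stoichiometry table, a gene set and an objective reaction. Flux bounds are
#' in mmol/gDCW/h and exchange reactions are written so that positive flux is
#' production (secretion) and negative flux is consumption (uptake).
#'
#' @param id Model identifier.
#' @param compartments Named character vector, code -> name. Codes follow the
#'   usual single/double letter convention (c cytosol, e extracellular,
#'   m mitochondrion, r endoplasmic reticulum, l lipid particle, x peroxisome,
#'   ...); any code set is allowed.
#' @param mets Data frame with columns `id`, `name`, `compartment`, `formula`
#'   (NA for pseudo-species), `mw` (annotated molecular weight in g/mol, NA to
#'   derive from the formula).
#' @param rxns Data frame with columns `id`, `name`, `lb`, `ub`, `gpr`
#'   (boolean gene rule string, NA if none), `subsystem`, `pseudo` (logical:
#'   biomass/pool/demand/dissipation pseudo-reactions).
#' @param stoich Data frame with columns `rxn`, `met`, `coef`; negative
#'   coefficients are consumed species.
#' @param genes Character vector of gene ids.
#' @param objective Reaction id of the objective (usually the biomass
#'   reaction).
#' @return An object of class `gem`.
#' @export
new_gem <- function(id, compartments, mets, rxns, stoich,
                    genes = character(), objective = NA_character_) {
  mets <- as.data.frame(mets, stringsAsFactors = FALSE)
  rxns <- as.data.frame(rxns, stringsAsFactors = FALSE)
  stoich <- as.data.frame(stoich, stringsAsFactors = FALSE)
  if (!"mw" %in% names(mets)) mets$mw <- NA_real_
  if (!"pseudo" %in% names(rxns)) rxns$pseudo <- FALSE
  if (!"subsystem" %in% names(rxns)) rxns$subsystem <- NA_character_
  if (!"gpr" %in% names(rxns)) rxns$gpr <- NA_character_
  model <- structure(
    list(id = id, compartments = compartments, mets = mets, rxns = rxns,
         stoich = stoich, genes = genes, objective = objective),
    class = "gem")
  validate_gem(model)
  model
}

#' Validate structural invariants of a model
#'
#' Checks id uniqueness, declared compartments, bound ordering, stoichiometry
#' references and the exchange-reaction convention (single extracellular
#' species). Called by [new_gem()]; call it again after manual edits.
#'
#' @param model A `gem`.
#' @return The model, invisibly; errors on violation.
#' @export
validate_gem <- function(model) {
  stopifnot(inherits(model, "gem"))
  if (anyDuplicated(model$mets$id)) stop("duplicate metabolite ids", call. = FALSE)
  if (anyDuplicated(model$rxns$id)) stop("duplicate reaction ids", call. = FALSE)
  bad_cmp <- setdiff(model$mets$compartment, names(model$compartments))
  if (length(bad_cmp)) {
    stop("undeclared compartment(s): ", paste(bad_cmp, collapse = ", "),
         call. = FALSE)
  }
  if (any(model$rxns$lb > model$rxns$ub)) {
    stop("lower bound exceeds upper bound for: ",
         paste(model$rxns$id[model$rxns$lb > model$rxns$ub], collapse = ", "),
         call. = FALSE)
  }
  bad_met <- setdiff(model$stoich$met, model$mets$id)
  if (length(bad_met)) {
    stop("stoichiometry references undeclared metabolite(s): ",
         paste(bad_met, collapse = ", "), call. = FALSE)
  }
  bad_rxn <- setdiff(model$stoich$rxn, model$rxns$id)
  if (length(bad_rxn)) {
    stop("stoichiometry references undeclared reaction(s): ",
         paste(bad_rxn, collapse = ", "), call. = FALSE)
  }
  if (!is.na(model$objective) && !model$objective %in% model$rxns$id) {
    stop("objective reaction not in model: ", model$objective, call. = FALSE)
  }
  invisible(model)
}

#' @export
print.gem <- function(x, ...) {
  cls <- classify_reactions(x)
  cat(sprintf("<gem> %s: %d reactions, %d metabolites, %d genes, %d compartments\n",
              x$id, nrow(x$rxns), nrow(x$mets), length(x$genes),
              length(x$compartments)))
  cat("  categories:",
      paste(sprintf("%s=%d", names(cls$counts), cls$counts), collapse = " "),
      "\n")
  cat("  objective:", x$objective, "\n")
  invisible(x)
}

#' Stoichiometric matrix of a model
#'
#' Rows are metabolites in the order of `model$mets$id`, columns are reactions
#' in the order of `model$rxns$id`; entry (i, j) is the signed coefficient of
#' metabolite i in reaction j (negative = consumed). Returned as a sparse
#' `Matrix::dgCMatrix` with dimnames.
#'
#' @param model A `gem`.
#' @return Sparse matrix S such that steady state is `S %*% v = 0`.
#' @export
stoichiometric_matrix <- function(model) {
  validate_gem(model)
  i <- match(model$stoich$met, model$mets$id)
  j <- match(model$stoich$rxn, model$rxns$id)
  Matrix::sparseMatrix(
    i = i, j = j, x = model$stoich$coef,
    dims = c(nrow(model$mets), nrow(model$rxns)),
    dimnames = list(model$mets$id, model$rxns$id))
}

#' Classify reactions by network structure
#'
#' Categories are derived from structure, not trusted from annotations:
#' the objective/biomass reaction and explicitly flagged pseudo-reactions are
#' set aside first; a reaction touching exactly one metabolite that lives in
#' the extracellular compartment is an exchange; a reaction spanning two or
#' more compartments is a transport; everything else is metabolic.
#'
#' @param model A `gem`.
#' @param extracellular Compartment code of the extracellular space.
#' @return List with `category` (named character vector per reaction) and
#'   `counts` (named integer vector over
#'   exchange/transport/metabolic/biomass/pseudo). Counts partition the
#'   reaction set.
#' @export
classify_reactions <- function(model, extracellular = "e") {
  met_cmp <- setNames(model$mets$compartment, model$mets$id)
  by_rxn <- split(model$stoich$met, model$stoich$rxn)
  category <- setNames(rep("metabolic", nrow(model$rxns)), model$rxns$id)
  for (rid in model$rxns$id) {
    mets <- by_rxn[[rid]]
    if (is.null(mets)) { category[rid] <- "pseudo"; next }
    cmps <- unique(met_cmp[mets])
    if (length(mets) == 1L && identical(unname(cmps), extracellular)) {
      category[rid] <- "exchange"
    } else if (length(cmps) >= 2L) {
      category[rid] <- "transport"
    }
  }
  is_biomass <- startsWith(model$rxns$id, "BIOMASS")
  if (!is.na(model$objective)) {
    is_biomass <- is_biomass | model$rxns$id == model$objective
  }
  flagged <- model$rxns$pseudo & !is_biomass
  category[model$rxns$id[flagged]] <- "pseudo"
  category[model$rxns$id[is_biomass]] <- "biomass"
  lev <- c("exchange", "transport", "metabolic", "biomass", "pseudo")
  counts <- table(factor(category, levels = lev))
  list(category = category,
       counts = setNames(as.integer(counts), lev))
}

# ---- gene-protein-reaction rules -------------------------------------------

#' Parse a gene-protein-reaction rule
#'
#' Rules are boolean expressions over gene ids with `and`/`or` (case
#' insensitive, `&`/`|` also accepted) and parentheses, e.g.
#' `"(g1 and g2) or g3"`. The result is a tree: a leaf is a gene id string, an
#' inner node is `list(op = "and"|"or", args = list(...))`.
#'
#' @param rule Rule string.
#' @return Parse tree, or NULL for an empty/NA rule.
#' @export
parse_gpr <- function(rule) {
  if (is.null(rule) || length(rule) == 0L || is.na(rule) || !nzchar(trimws(rule))) {
    return(NULL)
  }
  s <- gsub("&&?", " and ", rule)
  s <- gsub("\\|\\|?", " or ", s)
  toks <- regmatches(s, gregexpr("\\(|\\)|[^()[:space:]]+", s))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  parse_or <- function() {
    args <- list(parse_and())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      take()
      args <- c(args, list(parse_and()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
  }
  parse_and <- function() {
    args <- list(parse_atom())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      take()
      args <- c(args, list(parse_atom()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
  }
  parse_atom <- function() {
    t <- take()
    if (is.na(t)) stop("malformed gene rule: ", rule, call. = FALSE)
    if (t == "(") {
      e <- parse_or()
      if (!identical(take(), ")")) {
        stop("malformed gene rule (unbalanced parenthesis): ", rule, call. = FALSE)
      }
      return(e)
    }
    if (t == ")" || tolower(t) %in% c("and", "or")) {
      stop("malformed gene rule: ", rule, call. = FALSE)
    }
    t
  }
  tree <- parse_or()
  if (pos <= length(toks)) stop("malformed gene rule: ", rule, call. = FALSE)
  tree
}

#' Evaluate a gene rule under a set of deleted genes
#'
#' Genes in `deleted` are absent (FALSE), all other leaves present (TRUE);
#' `and` requires all children, `or` any child. A reaction without a rule is
#' unaffected by any deletion (callers should treat a NULL tree as TRUE).
#'
#' @param gpr Parse tree from [parse_gpr()] or a rule string.
#' @param deleted Character vector of deleted gene ids.
#' @return TRUE if the reaction retains catalysis.
#' @export
evaluate_gpr <- function(gpr, deleted = character()) {
  if (is.character(gpr) && length(gpr) == 1L && !is.na(gpr) &&
      grepl("[()[:space:]&|]", gpr)) {
    gpr <- parse_gpr(gpr)
  }
  if (is.null(gpr)) return(TRUE)
  if (is.character(gpr)) return(!gpr %in% deleted)
  if (!is.list(gpr) || is.null(gpr$op)) stop("malformed gene rule tree", call. = FALSE)
  vals <- vapply(gpr$args, evaluate_gpr, logical(1), deleted = deleted)
  if (gpr$op == "and") all(vals) else any(vals)
}

#' Genes appearing in a gene-rule tree
#' @keywords internal
gpr_genes <- function(gpr) {
  if (is.null(gpr)) return(character())
  if (is.character(gpr)) return(gpr)
  unique(unlist(lapply(gpr$args, gpr_genes)))
}

# ---- mass balance ----------------------------------------------------------

#' Elemental mass-balance report
#'
#' For every reaction with full formula coverage, the per-element imbalance is
#' the stoichiometry-weighted sum of atom counts; a reaction is balanced when
#' all imbalances are zero within `tol`. Reactions involving formula-less
#' (pseudo) species are reported as not assessable rather than failed, and
#' exchange/biomass/pseudo reactions are never expected to balance.
#'
#' @param model A `gem`.
#' @param tol Absolute tolerance on atom counts.
#' @return Data frame with one row per reaction: `rxn`, `category`,
#'   `assessable`, `balanced`, and one `imb_<element>` column per element.
#' @export
mass_balance_report <- function(model, tol = 1e-6) {
  cls <- classify_reactions(model)$category
  emat <- element_matrix(model$mets$formula)
  rownames(emat) <- model$mets$id
  elems <- colnames(emat)
  out <- data.frame(rxn = model$rxns$id,
                    category = unname(cls[model$rxns$id]),
                    assessable = FALSE, balanced = NA,
                    stringsAsFactors = FALSE)
  imb <- matrix(NA_real_, nrow(out), length(elems),
                dimnames = list(out$rxn, paste0("imb_", elems)))
  by_rxn <- split(seq_len(nrow(model$stoich)), model$stoich$rxn)
  for (rid in names(by_rxn)) {
    idx <- by_rxn[[rid]]
    mets <- model$stoich$met[idx]
    coefs <- model$stoich$coef[idx]
    rows <- emat[mets, , drop = FALSE]
    if (anyNA(rows)) next
    k <- match(rid, out$rxn)
    out$assessable[k] <- TRUE
    v <- colSums(rows * coefs)
    imb[k, ] <- v
    out$balanced[k] <- all(abs(v) <= tol)
  }
  # exchanges and pseudo/biomass reactions are boundary reactions by design
  boundary <- out$category %in% c("exchange", "biomass", "pseudo")
  out$assessable[boundary] <- FALSE
  out$balanced[boundary] <- NA
  cbind(out, imb)
}
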