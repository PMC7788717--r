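#' Standard atomic weights
#'
#' IUPAC 2021 standard atomic weights, rounded to at most four significant
#' decimals, for the elements that occur in metabolic reconstructions of
#' yeast. Used for molecular weights and elemental mass-balance checks.
#'
#' @format Named numeric vector, g/mol per atom.
#' @keywords internal
ATOMIC_MASSES <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974, S = 32.06,
  Na = 22.990, K = 39.098, Cl = 35.45, Fe = 55.845, Mg = 24.305,
  Ca = 40.078, Zn = 65.38, Cu = 63.546, Mn = 54.938, Se = 78.971
)

#' Parse an elemental formula string
#'
#' Formulas use standard element symbols with optional integer counts, e.g.
#' `"C6H12O6"`. Fractional counts are accepted for averaged (lumped) species.
#'
#' @param formula A single formula string.
#' @return Named numeric vector of atom counts per element.
#' @examples
#' parse_formula("C3H8O3")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  if (is.na(formula) || !nzchar(formula)) {
    stop("empty formula", call. = FALSE)
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", formula, perl = TRUE)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula)) {
    stop("cannot parse formula: ", formula, call. = FALSE)
  }
  counts <- numeric(0)
  for (tok in toks) {
    sym <- sub("^([A-Z][a-z]?).*$", "\\1", tok)
    num <- sub("^[A-Z][a-z]?", "", tok)
    n <- if (nzchar(num)) as.numeric(num) else 1
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0) + n
  }
  counts
}

#' Molecular weight of an elemental formula
#'
#' @param formula Formula string, e.g. `"C6H12O6"`.
#' @param unit `"g/mol"` (default) or `"g/mmol"`. All biomass standardization
#'   arithmetic in this package is done on the g/mmol scale (g/mol divided by
#'   1000), the natural scale when fluxes are mmol/gDCW/h.
#' @return Molecular weight as a single number.
#' @examples
#' molecular_weight("C3H8O3")           # glycerol, 92.094
#' molecular_weight("C6H12O6", "g/mmol")
#' @export
molecular_weight <- function(formula, unit = c("g/mol", "g/mmol")) {
  unit <- match.arg(unit)
  counts <- parse_formula(formula)
  unknown <- setdiff(names(counts), names(ATOMIC_MASSES))
  if (length(unknown)) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  mw <- sum(counts * ATOMIC_MASSES[names(counts)])
  if (unit == "g/mmol") mw / 1000 else mw
}

#' Elemental composition matrix for a set of formulas
#'
#' @param formulas Character vector (NA allowed, yields NA rows).
#' @return Matrix (length(formulas) x elements) of atom counts.
#' @keywords internal
element_matrix <- function(formulas) {
  parsed <- lapply(formulas, function(f) {
    if (is.na(f) || !nzchar(f)) return(NULL)
    parse_formula(f)
  })
  elems <- sort(unique(unlist(lapply(parsed, names))))
  out <- matrix(NA_real_, length(formulas), length(elems),
                dimnames = list(NULL, elems))
  for (i in seq_along(parsed)) {
    if (is.null(parsed[[i]])) next
    row <- setNames(numeric(length(elems)), elems)
    row[names(parsed[[i]])] <- parsed[[i]]
    out[i, ] <- row
  }
  out
}
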