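# Shared fixtures, built once per test run.

toy_cache <- new.env(parent = emptyenv())

get_toy <- function() {
  if (is.null(toy_cache$tg)) toy_cache$tg <- build_toy_gem()
  toy_cache$tg
}

# Tiny linear chain: EX_A (uptake) -> A -> B -> EX_B (secretion).
chain_model <- function(uptake = 5) {
  new_gem(
    id = "chain", compartments = c(e = "extracellular", c = "cytosol"),
    mets = data.frame(id = c("A_e", "A_c", "B_c", "B_e"),
                      name = c("A", "A", "B", "B"),
                      compartment = c("e", "c", "c", "e"),
                      formula = c("C2H4O2", "C2H4O2", "C2H4O2", "C2H4O2"),
                      mw = NA_real_, stringsAsFactors = FALSE),
    rxns = data.frame(id = c("EX_A", "TA", "R1", "TB", "EX_B"),
                      name = c("A exchange", "A transport", "A to B",
                               "B transport", "B exchange"),
                      lb = c(-uptake, 0, 0, 0, 0), ub = 1000,
                      gpr = c(NA, NA, "g1 or g2", NA, NA),
                      subsystem = NA_character_, pseudo = FALSE,
                      stringsAsFactors = FALSE),
    stoich = data.frame(
      rxn = c("EX_A", "TA", "TA", "R1", "R1", "TB", "TB", "EX_B"),
      met = c("A_e", "A_e", "A_c", "A_c", "B_c", "B_c", "B_e", "B_e"),
      coef = c(-1, -1, 1, -1, 1, -1, 1, -1), stringsAsFactors = FALSE),
    genes = c("g1", "g2"), objective = "EX_B")
}

# Two free reversible reactions with no metabolites: an axis-aligned box.
box_model <- function(bounds = c(-1, 1), k = 2) {
  new_gem(
    id = "box", compartments = c(e = "extracellular"),
    mets = data.frame(id = character(), name = character(),
                      compartment = character(), formula = character(),
                      mw = numeric(), stringsAsFactors = FALSE),
    rxns = data.frame(id = paste0("R", seq_len(k)), name = paste0("R", seq_len(k)),
                      lb = bounds[1], ub = bounds[2], gpr = NA_character_,
                      subsystem = NA_character_, pseudo = FALSE,
                      stringsAsFactors = FALSE),
    stoich = data.frame(rxn = character(), met = character(), coef = numeric(),
                        stringsAsFactors = FALSE),
    objective = "R1")
}

# --- independent LP oracles -------------------------------------------------

# pracma::linprog (unrelated simplex code) on the shifted nonnegative form.
lp_oracle_pracma <- function(A, b, obj, lb, ub, maximize = TRUE) {
  skip_if_not_installed("pracma")
  A <- as.matrix(A)
  n <- ncol(A)
  beq <- b - as.numeric(A %*% lb)
  r <- pracma::linprog(obj, A = diag(1, n), b = ub - lb, Aeq = A, beq = beq,
                       maximize = maximize, maxiter = 5000)
  if (is.null(r$x)) return(NULL)
  sum(obj * (r$x + lb))
}

# Exhaustive basic-feasible-solution enumeration: for S v = 0 with bounded
# variables, every vertex has >= n - rank(S) variables at a bound. Tiny
# problems only.
lp_oracle_enum <- function(A, obj, lb, ub, maximize = TRUE) {
  A <- as.matrix(A)
  n <- ncol(A); m <- nrow(A)
  r <- qr(A)$rank
  free_k <- r
  best <- NULL
  combos <- utils::combn(n, n - free_k, simplify = FALSE)
  for (nb in combos) {
    basic <- setdiff(seq_len(n), nb)
    grids <- expand.grid(rep(list(c(1, 2)), length(nb)))
    for (g in seq_len(nrow(grids))) {
      x <- numeric(n)
      x[nb] <- ifelse(unlist(grids[g, ]) == 1, lb[nb], ub[nb])
      if (length(basic)) {
        B <- A[, basic, drop = FALSE]
        rhs <- -as.numeric(A[, nb, drop = FALSE] %*% x[nb])
        sol <- tryCatch(qr.solve(B, rhs), error = function(e) NULL)
        if (is.null(sol)) next
        if (max(abs(B %*% sol - rhs)) > 1e-8) next
        x[basic] <- sol
      }
      if (any(x < lb - 1e-9) || any(x > ub + 1e-9)) next
      if (max(abs(A %*% x)) > 1e-8) next
      val <- sum(obj * x)
      if (is.null(best) || (maximize && val > best) || (!maximize && val < best)) {
        best <- val
      }
    }
  }
  best
}

# scipy HiGHS through the system python: a genuinely foreign LP code path.
lp_oracle_scipy <- function(A, obj, lb, ub, maximize = TRUE) {
  python <- Sys.which("python")
  if (!nzchar(python)) python <- Sys.which("python3")
  skip_if(!nzchar(python), "no python interpreter available")
  A <- as.matrix(A)
  fin <- tempfile(fileext = ".json"); fout <- tempfile(fileext = ".json")
  jsonlite::write_json(list(A = A, c = obj, lb = lb, ub = ub,
                            maximize = maximize),
                       fin, digits = NA, matrix = "rowmajor")
  script <- paste(
    "import json, sys",
    "import numpy as np",
    "from scipy.optimize import linprog",
    sprintf("d = json.load(open(%s))", deparse(fin)),
    "A = np.array(d['A']); c = np.array(d['c'], float)",
    "sgn = -1.0 if d['maximize'][0] else 1.0",
    "res = linprog(sgn*c, A_eq=A, b_eq=np.zeros(A.shape[0]),",
    "              bounds=list(zip(d['lb'], d['ub'])), method='highs')",
    "out = {'status': int(res.status), 'fun': None if res.fun is None else sgn*res.fun}",
    sprintf("json.dump(out, open(%s, 'w'))", deparse(fout)),
    sep = "\n")
  sf <- tempfile(fileext = ".py"); writeLines(script, sf)
  st <- system2(python, sf, stdout = TRUE, stderr = TRUE)
  skip_if(!file.exists(fout), paste("scipy oracle failed:", paste(st, collapse = " ")))
  res <- jsonlite::read_json(fout)
  if (res$status != 0) return(NULL)
  res$fun
}
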