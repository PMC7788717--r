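#' @title Uniform flux sampling and condition comparison
#' @description Artificial-centering hit-and-run sampling of the bounded
#'   steady-state flux polytope `{v : S v = 0, lb <= v <= ub}`, with warmup
#'   points taken from flux variability optima, and Z-score comparison of
#'   per-reaction flux distributions between a condition and the reference
#'   C/N ratio.
#' @name flux-sampling
NULL

#' Sample the steady-state flux polytope
#'
#' Hit-and-run chain with artificial centering: directions are drawn through
#' the running center from randomly chosen warmup points (flux variability
#' optima, i.e. extreme points of the polytope), so every direction lies in
#' the feasible affine subspace, including along fixed (lb = ub) coordinates.
#' Numerical drift off the `S v = 0` subspace is removed by orthogonal
#' projection onto the null space at every recorded point.
#'
#' @param model A `gem` with all condition constraints applied.
#' @param n Number of sample points (the full analyses use 5000).
#' @param seed RNG seed; a fixed seed gives an identical sample matrix.
#' @param steps_per_point Chain steps between recorded points.
#' @param warmup_reactions Reactions whose variability optima seed the chain
#'   (default: all). Fewer warmup reactions trade mixing for speed.
#' @param check_tol Tolerance for the membership assertion on stored points.
#' @return Object of class `sampling_result`: `points` (n x reactions
#'   matrix), `center`, `n`, `seed`, `steps_per_point`, `warmup_size`, and
#'   `fva` (the warmup variability table).
#' @export
sample_fluxes <- function(model, n = 5000, seed = 1, steps_per_point = 8,
                          warmup_reactions = model$rxns$id,
                          check_tol = 1e-6) {
  S <- as.matrix(stoichiometric_matrix(model))
  lb <- model$rxns$lb; ub <- model$rxns$ub
  nv <- ncol(S)
  feas <- solve_lp(S, NULL, numeric(nv), lb, ub, sense = "max")
  if (feas$status != "optimal") {
    stop("flux polytope is empty (LP status: ", feas$status, ")", call. = FALSE)
  }
  fv <- fva(model, reactions = warmup_reactions)
  W <- unique(round(attr(fv, "points"), 12))
  if (nrow(W) < 2L) stop("degenerate polytope: no warmup spread", call. = FALSE)

  # orthonormal basis of the row space of S, for null-space projection
  qrS <- qr(t(S))
  r <- qrS$rank
  Q1 <- if (r > 0) qr.Q(qrS)[, seq_len(r), drop = FALSE] else NULL
  project <- function(x) {
    if (is.null(Q1)) return(x)
    x - Q1 %*% crossprod(Q1, x)
  }

  set.seed(seed)
  center <- colMeans(W)
  x <- as.numeric(center)
  pts <- matrix(NA_real_, n, nv, dimnames = list(NULL, model$rxns$id))
  total <- 0L; recorded <- 0L
  while (recorded < n) {
    w <- W[sample.int(nrow(W), 1L), ]
    d <- w - center
    nd <- sqrt(sum(d^2))
    if (nd < 1e-12) next
    d <- d / nd
    act <- abs(d) > 1e-11
    if (!any(act)) next
    hi <- (ub[act] - x[act]) / d[act]
    lo <- (lb[act] - x[act]) / d[act]
    t_max <- min(pmax(hi, lo)); t_min <- max(pmin(hi, lo))
    if (t_max - t_min < 1e-12) next
    x <- x + stats::runif(1, t_min, t_max) * d
    total <- total + 1L
    # running center update (artificial centering)
    center <- center + (x - center) / (total + nrow(W))
    if (total %% steps_per_point == 0L) {
      x <- as.numeric(project(x))
      x <- pmin(pmax(x, lb), ub)
      recorded <- recorded + 1L
      pts[recorded, ] <- x
    }
  }
  resid <- if (nrow(S)) max(abs(pts %*% t(S))) else 0
  if (resid > check_tol) {
    stop(sprintf("sampled points violate steady state (max |Sv| = %.3g)", resid),
         call. = FALSE)
  }
  structure(list(points = pts, center = as.numeric(center), n = n, seed = seed,
                 steps_per_point = steps_per_point, warmup_size = nrow(W),
                 fva = fv),
            class = "sampling_result")
}

#' @export
print.sampling_result <- function(x, ...) {
  cat(sprintf("<sampling_result> %d points x %d reactions (seed %s, %d warmup)\n",
              nrow(x$points), ncol(x$points), format(x$seed), x$warmup_size))
  invisible(x)
}

#' Per-reaction summary of a sampling result
#'
#' @param object A `sampling_result`.
#' @param ... Unused.
#' @return Data frame `rxn`, `mean`, `sd`, `se`.
#' @export
summary.sampling_result <- function(object, ...) {
  m <- colMeans(object$points)
  s <- apply(object$points, 2, stats::sd)
  data.frame(rxn = colnames(object$points), mean = m, sd = s,
             se = s / sqrt(nrow(object$points)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Z-scores of flux shifts between two sampled conditions
#'
#' For each reaction, `Z = (mean_cond - mean_ref) / sqrt(sd_cond^2 +
#' sd_ref^2)`; positive Z means the flux increased relative to the reference
#' condition. Z is zero (not NaN) when both distributions are degenerate and
#' equal.
#'
#' @param ref Reference `sampling_result` (the C/N = 6 g/g condition in the
#'   lipid analyses).
#' @param cond Condition `sampling_result` over the same reaction index.
#' @param subsystems Optional named vector mapping reaction id -> subsystem
#'   tag carried into the output.
#' @return Data frame of class `zscore_table`: `rxn`, `mean_ref`, `sd_ref`,
#'   `mean_cond`, `sd_cond`, `z`, `subsystem`.
#' @export
zscore_compare <- function(ref, cond, subsystems = NULL) {
  if (!identical(colnames(ref$points), colnames(cond$points))) {
    stop("reaction indices differ between conditions", call. = FALSE)
  }
  m0 <- colMeans(ref$points);  s0 <- apply(ref$points, 2, stats::sd)
  m1 <- colMeans(cond$points); s1 <- apply(cond$points, 2, stats::sd)
  denom <- sqrt(s0^2 + s1^2)
  z <- ifelse(denom > 0, (m1 - m0) / denom, 0)
  out <- data.frame(rxn = colnames(ref$points),
                    mean_ref = m0, sd_ref = s0, mean_cond = m1, sd_cond = s1,
                    z = z,
                    subsystem = if (is.null(subsystems)) NA_character_
                                else unname(subsystems[colnames(ref$points)]),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("zscore_table", class(out))
  out
}

#' Sample a series of C/N conditions and compare to the reference
#'
#' For each carbon level and each C/N ratio: derive the carbon-source and
#' nitrogen uptake rates, install the condition-specific biomass, apply the
#' lipid-production protocol constraints (biomass window), sample the
#' constrained polytope, and compute Z-scores against the C/N = `reference_cn`
#' condition at the same carbon level.
#'
#' @param model A `gem` (minimal medium will be applied).
#' @param cn_list C/N ratios (g/g); the full analysis uses
#'   6, 8, 10, 12, 24, 30, 36, 48, 60, 90, 120, 180, 240.
#' @param carbon_grams Carbon amounts in grams; the analysis uses 16, 24, 32.
#'   Amounts are mapped to chemostat uptake rates with
#'   [carbon_grams_to_uptake()].
#' @param carbon_exchange,nitrogen_exchange Exchange reaction ids; the
#'   carbon-level series uses glycerol with ammonium.
#' @param n,seed,steps_per_point,warmup_reactions Sampler settings (see
#'   [sample_fluxes()]); the seed is advanced deterministically per condition.
#' @param reference_cn Reference C/N (g/g) for Z-scores.
#' @param gam Growth-associated maintenance.
#' @return List of per-carbon-level lists: `reference` (`sampling_result`)
#'   and `conditions` (per C/N: `cn`, `sample`, `zscores`, `protocol`).
#'   Infeasible conditions are recorded with NULL results.
#' @export
condition_series <- function(model, cn_list, carbon_grams = 16,
                             carbon_exchange = "EX_glyc",
                             nitrogen_exchange = "EX_nh4",
                             n = 500, seed = 1, steps_per_point = 8,
                             warmup_reactions = NULL,
                             reference_cn = 6, gam = 60) {
  model <- set_minimal_medium(model)
  subsys <- setNames(model$rxns$subsystem, model$rxns$id)
  if (is.null(warmup_reactions)) warmup_reactions <- model$rxns$id
  sample_cn <- function(cn, c_g, sd_seed) {
    uC <- carbon_grams_to_uptake(c_g, model, carbon_exchange)
    uN <- nitrogen_uptake_for_cn(model, carbon_exchange, nitrogen_exchange,
                                 uC, cn)
    cond <- apply_cn_condition(model, carbon_exchange, nitrogen_exchange,
                               uC, uN, dynamic_biomass = TRUE, gam = gam)
    pr <- lipid_production_protocol(cond$model)
    if (pr$no_growth) return(list(cn = cn, sample = NULL, protocol = pr))
    smp <- sample_fluxes(pr$constrained_model, n = n, seed = sd_seed,
                         steps_per_point = steps_per_point,
                         warmup_reactions = warmup_reactions)
    list(cn = cn, sample = smp, protocol = pr)
  }
  out <- list()
  for (ci in seq_along(carbon_grams)) {
    c_g <- carbon_grams[ci]
    ref <- sample_cn(reference_cn, c_g, seed + 1000L * ci)
    if (is.null(ref$sample)) {
      stop("reference condition C/N = ", reference_cn, " infeasible at ",
           c_g, " g carbon", call. = FALSE)
    }
    conds <- list()
    for (k in seq_along(cn_list)) {
      res <- sample_cn(cn_list[k], c_g, seed + 1000L * ci + k)
      if (!is.null(res$sample) && cn_list[k] != reference_cn) {
        res$zscores <- zscore_compare(ref$sample, res$sample, subsys)
      }
      conds[[as.character(cn_list[k])]] <- res
    }
    out[[as.character(c_g)]] <- list(carbon_g = c_g, reference = ref,
                                     conditions = conds)
  }
  out
}

#' Convert a carbon amount in grams to a chemostat uptake rate
#'
#' The lipid analyses state carbon levels as grams; the model needs
#' mmol/gDCW/h. The convention here maps `c_g` grams of elemental carbon to
#' `25 * c_g / 12.011` mmol C per gDCW per hour (so 16 g falls in the
#' validated uptake decade), divided by the carbon atoms of the source.
#'
#' @param c_g Carbon amount in grams.
#' @param model A `gem`.
#' @param carbon_exchange Carbon-source exchange id.
#' @param scale mmol C per (g C / 12.011).
#' @return Uptake rate of the carbon-source compound, mmol/gDCW/h.
#' @export
carbon_grams_to_uptake <- function(c_g, model, carbon_exchange, scale = 25) {
  met <- model$stoich$met[model$stoich$rxn == carbon_exchange]
  f <- model$mets$formula[match(met, model$mets$id)]
  atoms <- parse_formula(f)[["C"]]
  scale * c_g / ATOMIC_MASSES[["C"]] / atoms
}

#' Nitrogen uptake realizing a target C/N (g/g) against a carbon uptake
#'
#' @param model A `gem`.
#' @param carbon_exchange,nitrogen_exchange Exchange ids.
#' @param carbon_uptake Carbon-source uptake, mmol/gDCW/h.
#' @param cn_gg Target C/N in g/g.
#' @return Nitrogen-source uptake, mmol/gDCW/h.
#' @export
nitrogen_uptake_for_cn <- function(model, carbon_exchange, nitrogen_exchange,
                                   carbon_uptake, cn_gg) {
  atoms <- function(ex, el) {
    met <- model$stoich$met[model$stoich$rxn == ex]
    parse_formula(model$mets$formula[match(met, model$mets$id)])[[el]]
  }
  gC <- carbon_uptake * atoms(carbon_exchange, "C") * ATOMIC_MASSES[["C"]]
  gN <- gC / cn_gg
  gN / (atoms(nitrogen_exchange, "N") * ATOMIC_MASSES[["N"]])
}
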