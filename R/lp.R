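#' Solve a bounded-variable linear program
#'
#' Solves `max/min c'x` subject to `A x = b` and `lb <= x <= ub` with a dense
#' two-phase revised simplex on bounded variables. This is the engine behind
#' all flux balance computations in the package; problem sizes there are a few
#' hundred variables, well within dense-simplex territory.
#'
#' Anti-cycling: Dantzig pricing is used until a run of degenerate pivots is
#' detected, then the method falls back to Bland's rule, which guarantees
#' termination. Warm starts are supported through the `basis` argument (as
#' returned in a previous solution), which is what makes flux variability
#' scans over many objectives cheap.
#'
#' @param A Constraint matrix (dense or `Matrix` sparse), m x n.
#' @param b Right-hand side, length m (0 for steady-state flux problems).
#' @param obj Objective coefficients, length n.
#' @param lb,ub Variable bounds, length n; `ub` may be `Inf`.
#' @param sense `"max"` or `"min"`.
#' @param basis Optional warm-start basis from a previous solution on the same
#'   constraint matrix.
#' @param tol Pivot/reduced-cost tolerance.
#' @param ftol Feasibility tolerance (phase-1 residual, bound clamping).
#' @param max_iter Iteration cap (default `100 * (n + m)`).
#' @return List with `status` ("optimal", "infeasible", "unbounded",
#'   "maxiter"), `objective`, `x` (length n), and `basis` for warm starts.
#' @export
solve_lp <- function(A, b = NULL, obj, lb, ub, sense = c("max", "min"),
                     basis = NULL, tol = 1e-9, ftol = 1e-8, max_iter = NULL) {
  sense <- match.arg(sense)
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  if (is.null(b)) b <- numeric(m)
  stopifnot(length(obj) == n, length(lb) == n, length(ub) == n, length(b) == m)
  if (any(lb > ub + 1e-12)) return(list(status = "infeasible", objective = NA_real_,
                                        x = rep(NA_real_, n), basis = NULL))
  cc <- if (sense == "max") -as.numeric(obj) else as.numeric(obj)
  if (is.null(max_iter)) max_iter <- 100L * (n + m)

  if (m == 0L) {  # pure box: optimum is attained at the favorable bounds
    xs <- ifelse(cc > 0, lb, ifelse(cc < 0, ub, pmin(pmax(0, lb), ub)))
    if (any(!is.finite(xs) & cc != 0)) {
      return(list(status = "unbounded",
                  objective = if (sense == "max") Inf else -Inf,
                  x = rep(NA_real_, n), basis = NULL))
    }
    xs[!is.finite(xs)] <- 0
    return(list(status = "optimal", objective = sum(obj * xs), x = xs,
                basis = integer()))
  }

  # augmented problem: n structural + m artificial columns
  ntot <- n + m
  Aall <- cbind(A, diag(1, m))
  LB <- c(lb, rep(0, m))
  UB <- c(ub, rep(Inf, m))

  # nonbasic starting values: the finite bound of smaller magnitude
  start_val <- function(j) {
    l <- LB[j]; u <- UB[j]
    if (!is.finite(l) && !is.finite(u)) return(0)
    if (!is.finite(l)) return(u)
    if (!is.finite(u)) return(l)
    if (abs(l) <= abs(u)) l else u
  }

  x <- vapply(seq_len(ntot), start_val, numeric(1))
  at_ub <- x == UB & LB != UB   # nonbasic-at-upper flags

  run_simplex <- function(cost, basis, x, at_ub, phase) {
    degen <- 0L
    for (it in seq_len(max_iter)) {
      B <- Aall[, basis, drop = FALSE]
      xB <- x[basis]
      y <- tryCatch(solve(t(B), cost[basis]),
                    error = function(e) NULL)
      if (is.null(y)) return(list(status = "singular"))
      nonbasic <- setdiff(seq_len(ntot), basis)
      d <- cost[nonbasic] - as.numeric(crossprod(Aall[, nonbasic, drop = FALSE], y))
      # eligibility: improve by increasing from lb or decreasing from ub
      sig <- ifelse(at_ub[nonbasic], -1, 1)
      score <- d * sig                       # want score < -tol
      elig <- which(score < -tol)
      if (!length(elig)) {
        return(list(status = "optimal", basis = basis, x = x, at_ub = at_ub))
      }
      k <- if (degen > 40L) elig[which.min(nonbasic[elig])]  # Bland
           else elig[which.min(score[elig])]                 # Dantzig
      q <- nonbasic[k]
      sigma <- if (at_ub[q]) -1 else 1
      w <- solve(B, Aall[, q])
      # ratio test: basic variables move by -sigma * t * w
      t_own <- if (is.finite(LB[q]) && is.finite(UB[q])) UB[q] - LB[q] else Inf
      t_best <- t_own; leave <- 0L; leave_to_ub <- FALSE
      for (i in seq_len(m)) {
        wi <- sigma * w[i]
        if (wi > ftol) {
          lim <- (xB[i] - LB[basis[i]]) / wi
          if (lim < t_best - 1e-12) { t_best <- lim; leave <- i; leave_to_ub <- FALSE }
        } else if (wi < -ftol) {
          lim <- (UB[basis[i]] - xB[i]) / (-wi)
          if (lim < t_best - 1e-12) { t_best <- lim; leave <- i; leave_to_ub <- TRUE }
        }
      }
      if (!is.finite(t_best)) return(list(status = "unbounded"))
      t_best <- max(t_best, 0)
      degen <- if (t_best <= ftol) degen + 1L else 0L
      # apply step
      x[basis] <- xB - sigma * t_best * w
      x[q] <- x[q] + sigma * t_best
      if (leave == 0L) {
        # bound-to-bound move, basis unchanged
        at_ub[q] <- !at_ub[q]
        x[q] <- if (at_ub[q]) UB[q] else LB[q]
      } else {
        p <- basis[leave]
        x[p] <- if (leave_to_ub) UB[p] else LB[p]
        at_ub[p] <- leave_to_ub
        basis[leave] <- q
        at_ub[q] <- FALSE
      }
    }
    list(status = "maxiter", basis = basis, x = x, at_ub = at_ub)
  }

  # --- try warm start -------------------------------------------------------
  phase1_needed <- TRUE
  if (!is.null(basis) && length(basis) == m && all(basis >= 1 & basis <= ntot)) {
    B <- Aall[, basis, drop = FALSE]
    nonbasic <- setdiff(seq_len(ntot), basis)
    xN <- x[nonbasic]
    xB <- tryCatch(
      solve(B, b - as.numeric(Aall[, nonbasic, drop = FALSE] %*% xN)),
      error = function(e) NULL)
    if (!is.null(xB) &&
        all(xB >= LB[basis] - 1e-7) && all(xB <= UB[basis] + 1e-7)) {
      x[basis] <- pmin(pmax(xB, LB[basis]), UB[basis])
      phase1_needed <- FALSE
    }
  }

  if (phase1_needed) {
    r <- b - as.numeric(Aall[, seq_len(n), drop = FALSE] %*% x[seq_len(n)])
    sgn <- ifelse(r >= 0, 1, -1)
    Aall[, n + seq_len(m)] <- diag(sgn, m)
    x[n + seq_len(m)] <- abs(r)
    basis <- n + seq_len(m)
    at_ub[basis] <- FALSE
    c1 <- c(rep(0, n), rep(1, m))
    res1 <- run_simplex(c1, basis, x, at_ub, phase = 1L)
    if (res1$status %in% c("singular", "maxiter")) {
      return(list(status = if (res1$status == "singular") "infeasible" else "maxiter",
                  objective = NA_real_, x = rep(NA_real_, n), basis = NULL))
    }
    if (res1$status == "unbounded" ||
        sum(res1$x[n + seq_len(m)]) > 1e-6) {
      return(list(status = "infeasible", objective = NA_real_,
                  x = rep(NA_real_, n), basis = NULL))
    }
    basis <- res1$basis; x <- res1$x; at_ub <- res1$at_ub
  }

  # phase 2: freeze artificials at zero
  UB[n + seq_len(m)] <- 0
  x[n + seq_len(m)] <- pmin(x[n + seq_len(m)], 0)
  c2 <- c(cc, rep(0, m))
  res2 <- run_simplex(c2, basis, x, at_ub, phase = 2L)
  if (res2$status == "singular") {
    return(list(status = "infeasible", objective = NA_real_,
                x = rep(NA_real_, n), basis = NULL))
  }
  if (res2$status == "unbounded") {
    return(list(status = "unbounded", objective = if (sense == "max") Inf else -Inf,
                x = rep(NA_real_, n), basis = NULL))
  }
  xs <- res2$x[seq_len(n)]
  val <- sum(obj * xs)
  list(status = if (res2$status == "maxiter") "maxiter" else "optimal",
       objective = val, x = xs, basis = res2$basis)
}
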