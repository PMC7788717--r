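test_that("flow conservation on a linear chain", {
  m <- chain_model(uptake = 5)
  sol <- fba(m, objective = "EX_B")
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective, 5, tolerance = 1e-9)
  expect_equal(unname(sol$fluxes[c("EX_A", "R1", "EX_B")]), c(-5, 5, 5),
               tolerance = 1e-9)

  closed <- set_bounds(m, "EX_A", lb = 0)
  expect_equal(fba(closed, objective = "EX_B")$objective, 0, tolerance = 1e-12)
})

test_that("infeasible and unbounded problems are reported in status", {
  m <- chain_model(uptake = 1)
  m <- set_bounds(m, "EX_B", lb = 5, ub = 5)  # demands more than uptake allows
  expect_equal(fba(m, objective = "EX_B")$status, "infeasible")

  res <- solve_lp(matrix(c(1, -1), 1, 2), NULL, c(1, 0),
                  lb = c(-Inf, -Inf), ub = c(Inf, Inf), sense = "max")
  expect_equal(res$status, "unbounded")
})

test_that("simplex agrees with an unrelated simplex code on random LPs", {
  skip_if_not_installed("pracma")
  set.seed(101)
  for (trial in 1:40) {
    m <- sample(2:7, 1); n <- m + sample(1:7, 1)
    A <- matrix(round(stats::rnorm(m * n), 2), m, n)
    lb <- round(stats::runif(n, -5, 0), 2)
    ub <- round(stats::runif(n, 0.1, 5), 2)
    x0 <- lb + stats::runif(n) * (ub - lb)
    b <- as.numeric(A %*% x0)                 # feasible by construction
    obj <- round(stats::rnorm(n), 2)
    mine <- solve_lp(A, b, obj, lb, ub, sense = "max")
    ref <- lp_oracle_pracma(A, b, obj, lb, ub)
    expect_equal(mine$status, "optimal")
    if (!is.null(ref)) {
      expect_equal(mine$objective, ref, tolerance = 1e-6)
    }
  }
})

test_that("simplex agrees with exhaustive vertex enumeration on tiny LPs", {
  set.seed(202)
  for (trial in 1:25) {
    m <- sample(1:3, 1); n <- m + sample(1:4, 1)
    A <- matrix(sample(-2:2, m * n, replace = TRUE), m, n)
    lb <- round(stats::runif(n, -3, 0), 1)
    ub <- round(stats::runif(n, 0.5, 3), 1)
    obj <- sample(-3:3, n, replace = TRUE)
    mine <- solve_lp(A, NULL, obj, lb, ub, sense = "max")
    ref <- lp_oracle_enum(A, obj, lb, ub, maximize = TRUE)
    if (is.null(ref)) {
      expect_true(mine$status %in% c("infeasible", "optimal"))
    } else {
      expect_equal(mine$status, "optimal")
      expect_equal(mine$objective, ref, tolerance = 1e-7)
    }
  }
})

test_that("full-model FBA matches a foreign solver within 1e-6", {
  m <- get_toy()$model
  S <- stoichiometric_matrix(m)
  mine <- fba(m)
  ref <- lp_oracle_scipy(S, as.numeric(m$rxns$id == m$objective),
                         m$rxns$lb, m$rxns$ub, maximize = TRUE)
  expect_false(is.null(ref))
  expect_equal(mine$objective, ref, tolerance = 1e-6)
})

test_that("optimal solutions satisfy steady state and bounds", {
  m <- get_toy()$model
  sol <- fba(m)
  S <- stoichiometric_matrix(m)
  expect_lt(max(abs(as.numeric(S %*% sol$fluxes))), 1e-6)
  expect_true(all(sol$fluxes >= m$rxns$lb - 1e-9))
  expect_true(all(sol$fluxes <= m$rxns$ub + 1e-9))
})

test_that("warm-started FVA brackets the FBA optimum", {
  m <- chain_model(uptake = 3)
  fv <- fva(m, reactions = c("R1", "EX_B"))
  expect_equal(fv$min, c(0, 0), tolerance = 1e-9)
  expect_equal(fv$max, c(3, 3), tolerance = 1e-9)
  pts <- attr(fv, "points")
  expect_equal(nrow(pts), 4L)
  S <- as.matrix(stoichiometric_matrix(m))
  expect_lt(max(abs(pts %*% t(S))), 1e-6)
})
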