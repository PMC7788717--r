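test_that("box polytope sampling matches the uniform closed forms", {
  box <- box_model(bounds = c(-1, 1), k = 2)
  s <- sample_fluxes(box, n = 2000, seed = 42)
  se_mean <- sqrt((2^2 / 12) / 2000)
  expect_true(all(abs(colMeans(s$points)) < 3 * se_mean * 2))
  v <- apply(s$points, 2, stats::var)
  expect_true(all(abs(v - 1 / 3) < 0.05))
  expect_true(all(s$points >= -1 & s$points <= 1))

  # asymmetric box: mean at the midpoint
  box2 <- box_model(bounds = c(0, 4), k = 2)
  s2 <- sample_fluxes(box2, n = 2000, seed = 7)
  expect_true(all(abs(colMeans(s2$points) - 2) < 0.15))
})

test_that("sampling is reproducible for a fixed seed", {
  box <- box_model()
  a <- sample_fluxes(box, n = 300, seed = 13)
  b <- sample_fluxes(box, n = 300, seed = 13)
  expect_identical(a$points, b$points)
  c <- sample_fluxes(box, n = 300, seed = 14)
  expect_false(identical(a$points, c$points))
})

test_that("an empty polytope raises an informative error", {
  m <- chain_model(uptake = 1)
  m <- set_bounds(m, "EX_B", lb = 5, ub = 5)
  expect_error(sample_fluxes(m, n = 10), "empty")
})

test_that("sampled toy-model points satisfy the protocol constraints", {
  tg <- get_toy()
  m <- set_minimal_medium(tg$model)
  cond <- apply_cn_condition(m, "EX_glc", "EX_nh4", 10, 1)
  pr <- lipid_production_protocol(cond$model)
  mm <- pr$constrained_model
  s <- sample_fluxes(mm, n = 150, seed = 3)
  S <- as.matrix(stoichiometric_matrix(mm))
  expect_lt(max(abs(s$points %*% t(S))), 1e-6)
  expect_true(all(t(s$points) >= mm$rxns$lb - 1e-6))
  expect_true(all(t(s$points) <= mm$rxns$ub + 1e-6))
  # biomass window respected by every point
  expect_true(all(s$points[, "BIOMASS"] >= pr$biomass_bounds[1] - 1e-6))
  expect_true(all(s$points[, "BIOMASS"] <= pr$biomass_bounds[2] + 1e-6))
  # per-reaction means lie within the FVA intervals
  fv <- s$fva
  mu <- colMeans(s$points)[fv$rxn]
  expect_true(all(mu >= fv$min - 1e-6 & mu <= fv$max + 1e-6))
})

test_that("Z-scores: identity, closed-form shift, antisymmetry", {
  box <- box_model()
  a <- sample_fluxes(box, n = 400, seed = 1)
  z0 <- zscore_compare(a, a)
  expect_true(all(z0$z == 0))

  # adding a constant shift to one reaction gives Z = delta / (sd * sqrt(2))
  b <- a
  delta <- 0.35
  b$points[, 1] <- b$points[, 1] + delta
  z <- zscore_compare(a, b)
  sd1 <- stats::sd(a$points[, 1])
  expect_equal(z$z[1], delta / (sd1 * sqrt(2)), tolerance = 1e-9)
  expect_equal(z$z[2], 0)

  # antisymmetric under swapping reference and condition
  expect_equal(zscore_compare(b, a)$z, -z$z, tolerance = 1e-12)

  mismatched <- a
  colnames(mismatched$points) <- c("X1", "X2")
  expect_error(zscore_compare(a, mismatched), "indices differ")
})

test_that("condition series emits Z-score tables against the reference", {
  tg <- get_toy()
  res <- condition_series(tg$model, cn_list = c(6, 60), carbon_grams = 16,
                          n = 80, seed = 5)
  lvl <- res[["16"]]
  expect_equal(lvl$reference$cn, 6)
  expect_null(lvl$conditions[["6"]]$zscores)   # reference vs itself skipped
  zt <- lvl$conditions[["60"]]$zscores
  expect_s3_class(zt, "zscore_table")
  expect_equal(nrow(zt), nrow(tg$model$rxns))
  expect_true(all(is.finite(zt$z)))
})
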