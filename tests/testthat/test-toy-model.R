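test_that("default build grows on glucose minimal medium", {
  m <- get_toy()$model
  sol <- fba(m)
  expect_equal(sol$status, "optimal")
  expect_gt(sol$objective, 0.1)
})

test_that("manifest entries resolve against the generated model", {
  tg <- get_toy()
  expect_true(all(tg$manifest$lumped_reactions %in% tg$model$rxns$id))
  expect_true(all(tg$manifest$carbon_sources$exchange %in% tg$model$rxns$id))
  expect_true(all(tg$manifest$essential_genes %in% tg$model$genes))
  expect_true(all(tg$manifest$tracked %in% tg$model$rxns$id))
  expect_true(all(unlist(tg$manifest$pathways) %in% tg$model$rxns$id))
})

test_that("the lumped fatty acid synthase consumes 14 NADPH", {
  m <- get_toy()$model
  fas <- m$stoich[m$stoich$rxn == "FAS", ]
  expect_equal(fas$coef[fas$met == "nadph_c"], -14)
  expect_equal(fas$coef[fas$met == "malcoa_c"], -7)
  expect_equal(fas$coef[fas$met == "pmtcoa_c"], 1)
})

test_that("ethanol supports no growth by default, but does with the flag", {
  tg <- get_toy()
  m <- set_minimal_medium(tg$model)
  m <- set_bounds(m, "EX_etoh", lb = -30, ub = 0)
  sol <- fba(m)
  mu <- if (sol$status == "optimal") sol$objective else 0
  expect_lte(mu, 1e-6)

  withmod <- build_toy_gem(include_ethanol_assimilation = TRUE)$model
  m2 <- set_minimal_medium(withmod)
  m2 <- set_bounds(m2, "EX_etoh", lb = -30, ub = 0)
  expect_gt(fba(m2)$objective, 0.1)
})

test_that("ACL deletion abolishes growth and lipid production", {
  tg <- get_toy()
  ko <- knockout_growth(tg$model, tg$manifest$acl_gene)
  expect_lte(ko$mu, 1e-6)
  expect_lte(ko$lipid_flux, 1e-6)
  expect_true("ACL" %in% ko$disabled)
})

test_that("growth is possible on all five sugars/polyols at equal C-mol", {
  tg <- get_toy()
  m <- set_minimal_medium(tg$model)
  srcs <- setNames(tg$manifest$carbon_sources$exchange,
                   tg$manifest$carbon_sources$name)
  mus <- sapply(setdiff(names(srcs), "ethanol"), function(s) {
    up <- uptake_for_equal_cmol(s, "glucose", 10)
    mm <- set_bounds(m, srcs[[s]], lb = -up, ub = -up)
    sol <- fba(mm)
    if (sol$status == "optimal") sol$objective else 0
  })
  expect_true(all(mus > 0.1))
  expect_lt(mus[["glycerol"]], mus[["glucose"]])  # lower growth on glycerol
  expect_equal(mus[["fructose"]], mus[["glucose"]], tolerance = 1e-6)
})

test_that("bound jitter perturbs only metabolic caps, deterministically", {
  a <- build_toy_gem(seed = 3, bound_jitter = 0.05)
  b <- build_toy_gem(seed = 3, bound_jitter = 0.05)
  expect_identical(a$model$rxns, b$model$rxns)
  base <- get_toy()$model
  changed <- a$model$rxns$ub != base$rxns$ub
  expect_true(any(changed))
  cls <- classify_reactions(base)$category
  expect_true(all(cls[a$model$rxns$id[changed]] == "metabolic"))
})
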