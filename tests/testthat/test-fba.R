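test_that("minimal medium opens the stated exchanges and closes the rest", {
  m <- set_minimal_medium(get_toy()$model)
  expect_equal(m$rxns$lb[m$rxns$id == "EX_glc"], 0)
  expect_equal(m$rxns$lb[m$rxns$id == "EX_o2"], -1000)
  expect_equal(m$rxns$lb[m$rxns$id == "EX_nh4"], -1000)
  # no carbon source open: no growth (maintenance may even be infeasible)
  sol <- fba(m)
  mu <- if (sol$status == "optimal") sol$objective else 0
  expect_lte(mu, 1e-6)
  expect_warning(set_minimal_medium(get_toy()$model,
                                    unlimited = c("EX_o2", "EX_missing")),
                 "missing exchange")
})

test_that("equal C-mol normalization follows atom-count arithmetic", {
  expect_equal(uptake_for_equal_cmol("glycerol", "glucose", 10), 20)
  expect_equal(uptake_for_equal_cmol("sucrose", "glucose", 10), 5)
  expect_equal(uptake_for_equal_cmol("glucose", "glucose", 7.3), 7.3)
  expect_equal(uptake_for_equal_cmol("xylose", "glucose", 10), 12)
  expect_error(uptake_for_equal_cmol(0, "glucose", 10), "carbon-free")
})

test_that("lipid protocol applies the biomass window rule", {
  tg <- get_toy()
  m <- set_minimal_medium(tg$model)
  # high growth condition: window is [0.18, 0.20]
  cond <- apply_cn_condition(m, "EX_glc", "EX_nh4", 10, 3)
  pr <- lipid_production_protocol(cond$model)
  expect_gt(pr$mu_star, 0.2)
  expect_equal(pr$biomass_bounds, c(0.18, 0.20))
  expect_gt(pr$lipid_flux, 0)
  expect_gte(pr$lipid_synthesis, pr$lipid_flux)

  # low growth condition: window is [0.9 mu*, mu*]
  cond2 <- apply_cn_condition(m, "EX_glc", "EX_nh4", 1.5, 3)
  pr2 <- lipid_production_protocol(cond2$model)
  expect_lt(pr2$mu_star, 0.2)
  expect_equal(pr2$biomass_bounds, c(0.9, 1) * pr2$mu_star)

  # closing the lipid-body exchange zeroes the lipid flux
  closed <- set_bounds(cond$model, "EX_lipid_body", lb = 0, ub = 0)
  expect_equal(lipid_production_protocol(closed)$lipid_flux, 0)

  # no carbon: no growth flag, zero lipid
  none <- apply_cn_condition(m, "EX_glc", "EX_nh4", 0, 3)
  pr0 <- lipid_production_protocol(none$model)
  expect_true(pr0$no_growth)
  expect_equal(pr0$lipid_flux, 0)
})

test_that("lipid export needs high C/N when carbon is scarce", {
  tg <- get_toy()
  m <- set_minimal_medium(tg$model)
  lipid_at <- function(cn) {
    uC <- 2.5  # just enough glucose to reach the growth cap at rich nitrogen
    uN <- uC * 6 * 12.011 / cn / 14.007
    cond <- apply_cn_condition(m, "EX_glc", "EX_nh4", uC, uN)
    lipid_production_protocol(cond$model)$lipid_flux
  }
  low <- lipid_at(6); high <- lipid_at(120)
  expect_lt(low, 0.03)          # barely any lipid at C/N = 6
  expect_gt(high, 3 * low)      # several-fold more under nitrogen limitation
})

test_that("knockouts follow the gene rules", {
  tg <- get_toy()
  wt <- fba(tg$model)$objective
  none <- knockout_growth(tg$model, character())
  expect_equal(none$mu, wt, tolerance = 1e-9)

  # deleting one of two isoenzymes changes nothing (glycerol kinase pair)
  iso <- knockout_growth(tg$model, "gGUT1a")
  expect_equal(iso$mu, wt, tolerance = 1e-6)
  expect_false("GLYK" %in% iso$disabled)

  # deleting a subunit of an AND complex removes the reaction
  fas <- knockout_growth(tg$model, "gFAS1")
  expect_true("FAS" %in% fas$disabled)
  expect_lte(fas$mu, 1e-6)

  expect_error(knockout_growth(tg$model, "gNOSUCH"), "unknown gene")
})

test_that("growth screen records grid structure and known phenotypes", {
  tg <- get_toy()
  srcs <- c(glucose = "EX_glc", glycerol = "EX_glyc", ethanol = "EX_etoh")
  scr <- growth_screen(tg$model, srcs, c_uptakes = 10, n_uptakes = c(1, 5))
  expect_equal(nrow(scr), 6L)
  expect_true(all(scr$mu[scr$source == "ethanol"] <= 1e-6))
  for (nu in c(1, 5)) {
    expect_lt(scr$mu[scr$source == "glycerol" & scr$n_uptake == nu],
              scr$mu[scr$source == "glucose" & scr$n_uptake == nu])
  }
  # doubling C and N (same C/N) never decreases growth
  scr2 <- growth_screen(tg$model, srcs["glucose"], c_uptakes = c(5, 10),
                        n_uptakes = 2)
  expect_gte(scr2$mu[scr2$c_uptake == 10] + 1e-9,
             scr2$mu[scr2$c_uptake == 5])
})

test_that("no nitrogen source means no growth", {
  tg <- get_toy()
  m <- set_minimal_medium(tg$model)
  m <- set_bounds(m, c("EX_nh4", "EX_urea"), lb = 0)
  m <- set_bounds(m, "EX_glc", lb = -10, ub = -10)
  sol <- fba(m)
  mu <- if (sol$status == "optimal") sol$objective else 0
  expect_lte(mu, 1e-6)
})
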