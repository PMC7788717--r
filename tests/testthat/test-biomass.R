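test_that("C/N ratio of the two experimental media is reproduced", {
  medA <- medium_spec(data.frame(id = c("glycerol", "nh4cl"),
                                 conc_g_l = c(16, 1)))
  cnA <- cn_ratio_from_medium(medA)
  expect_equal(round(cnA$molar), 28)           # reported as 28
  expect_equal(cnA$molar, 27.88, tolerance = 0.01)

  medB <- medium_spec(data.frame(id = c("glycerol", "nh4cl"),
                                 conc_g_l = c(8, 5)))
  expect_equal(cn_ratio_from_medium(medB)$molar, 2.8, tolerance = 0.01)

  # equal mol C and mol N -> exactly 1 (CH4N2O has 1 C, 2 N; add 1 more C)
  med1 <- medium_spec(data.frame(id = c("x", "y"),
                                 formula = c("CH4N2O", "CO2"),
                                 conc_g_l = c(60.056, 44.009)))
  expect_equal(cn_ratio_from_medium(med1)$molar, 1, tolerance = 1e-9)
})

test_that("C/N ratios are invariant under scaling all concentrations", {
  base <- data.frame(id = c("glucose", "urea"), conc_g_l = c(10, 0.7))
  cn1 <- cn_ratio_from_medium(medium_spec(base))
  for (s in c(0.01, 3, 1000)) {
    scaled <- base; scaled$conc_g_l <- scaled$conc_g_l * s
    expect_equal(cn_ratio_from_medium(medium_spec(scaled))$molar, cn1$molar,
                 tolerance = 1e-12)
  }
})

test_that("molar to mass C/N conversion hits the critical-ratio identity", {
  expect_equal(cn_molar_to_mass(12.83), 11.0, tolerance = 0.005)
  expect_equal(cn_molar_to_mass(0), 0)
  expect_equal(cn_molar_to_mass(28), 28 * 12.011 / 14.007, tolerance = 1e-12)
  expect_error(cn_molar_to_mass(-1), "negative")
})

test_that("quadratic lipid-content model evaluates, clamps and peaks", {
  expect_equal(lipid_weight_percent(0), 1.9)
  expect_equal(lipid_weight_percent(100), 40.9, tolerance = 1e-9)
  vertex <- 0.59 / (2 * 0.002)
  expect_equal(vertex, 147.5)
  expect_equal(lipid_weight_percent(vertex), 45.4125, tolerance = 1e-9)
  # global maximum over the domain is the vertex value
  grid <- seq(0, 300, by = 0.25)
  expect_equal(max(lipid_weight_percent(grid)), lipid_weight_percent(vertex))
  # monotone non-decreasing up to the vertex
  expect_true(all(diff(lipid_weight_percent(seq(0, 147.5, 0.5))) >= 0))
  # clamped to [0, 79]
  expect_equal(lipid_weight_percent(1000), 0)
  expect_true(all(lipid_weight_percent(grid) <= 79))
})

test_that("starvation composition keeps 11% carbohydrate and sums to one", {
  c100 <- compose_biomass(100, "starvation")
  expect_equal(c100$w_C, 0.11)
  expect_equal(c100$w_other, 0.05)
  expect_equal(c100$w_TL, 0.409, tolerance = 1e-9)
  expect_equal(c100$w_P, 0.431, tolerance = 1e-9)

  c0 <- compose_biomass(0, "starvation")
  expect_equal(c0$w_TL, 0.019)
  expect_equal(c0$w_P, 0.821, tolerance = 1e-9)

  for (cn in c(0, 3, 6, 11, 60, 147.5, 240, 1000)) {
    comp <- compose_biomass(cn, "starvation")
    expect_equal(comp$w_C + comp$w_P + comp$w_TL + comp$w_other, 1)
    expect_equal(comp$w_C, 0.11)
    expect_true(all(unlist(comp[c("w_C", "w_P", "w_TL", "w_other")]) >= 0))
    expect_true(all(unlist(comp[c("w_C", "w_P", "w_TL", "w_other")]) <= 1))
  }
  rep <- compose_biomass(5, "replete")
  expect_equal(rep$w_C + rep$w_P + rep$w_TL + rep$w_other, 1)
})

test_that("acyl-CoA pool coefficients are as printed and recover the shares", {
  pool <- acyl_pool_reaction()
  expect_identical(pool$coef, c(0.24952, 0.096712, 0.55233, 0.067963))
  expect_equal(sum(pool$coef), 0.966525)
  fr <- acyl_pool_fractions()
  # weight shares recover the printed fatty-acid percentages (sum 99%)
  expect_equal(round(unname(fr)), c(25, 10, 57, 7))
  expect_equal(sum(fr), 99, tolerance = 0.2)
})

test_that("assembled biomass reaction is standardized to 1 g/mmol", {
  m <- get_toy()$model
  for (cn in c(0, 6, 28, 60, 120, 147.5, 240)) {
    comp <- compose_biomass(cn, "starvation")
    rx <- assemble_biomass_reaction(comp, m, gam = 60)
    expect_equal(attr(rx, "mw"), 1, tolerance = 1e-6)
    subs <- rx$coef[rx$met %in% c("carb_c", "prot_c", "lipid_c", "other_c")]
    expect_true(all(subs < 0))           # consumed
    m2 <- install_biomass(m, comp, gam = 60)
    expect_equal(biomass_mw(m2), 1, tolerance = 1e-6)
    # round-trip: coefficients x MWs recover the composition
    w <- composition_from_reaction(m2)
    expect_equal(unname(w), c(comp$w_C, comp$w_P, comp$w_TL, comp$w_other),
                 tolerance = 1e-9)
  }
  # determinism
  comp <- compose_biomass(60)
  expect_identical(assemble_biomass_reaction(comp, m),
                   assemble_biomass_reaction(comp, m))
})

test_that("TAG keeps 90% of the lipid pool by mass", {
  m <- get_toy()$model
  shares <- biomass_lipid_breakdown(m)
  expect_equal(unname(shares[["tag_c"]]), 90, tolerance = 1e-9)
  expect_equal(sum(shares), 100, tolerance = 1e-9)
  expect_equal(unname(shares[c("ps_c", "pe_c", "pc_c")]),
               rep(10 / 3, 3), tolerance = 1e-9)
})
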