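test_that("dissipation reactions are added once, for all eight carriers", {
  m <- add_dissipation_reactions(get_toy()$model)
  diss <- m$rxns$id[startsWith(m$rxns$id, "DISS_")]
  expect_length(diss, 8L)
  expect_setequal(sub("DISS_", "", diss),
                  c("atp", "ctp", "gtp", "utp", "nadh", "nadph", "fadh2",
                    "proton"))
  # flagged pseudo: the metabolic count is unchanged
  before <- classify_reactions(get_toy()$model)$counts
  after <- classify_reactions(m)$counts
  expect_equal(after[["metabolic"]], before[["metabolic"]])
  expect_equal(after[["pseudo"]], before[["pseudo"]] + 8L)
  # idempotent
  m2 <- add_dissipation_reactions(m)
  expect_identical(m2$rxns$id, m$rxns$id)
  # missing carriers: each skipped with a warning, none added
  small <- chain_model()
  w <- capture_warnings(small2 <- add_dissipation_reactions(small))
  expect_true(all(grepl("carrier missing", w)))
  expect_length(w, 8L)
  expect_equal(nrow(small2$rxns), nrow(small$rxns))
})

test_that("the shipped model passes the energy audit", {
  rep <- detect_energy_cycles(get_toy()$model)
  expect_true(rep$pass)
  expect_true(all(rep$maxima$max_flux <= 1e-6))
  expect_equal(nrow(rep$maxima), 8L)
})

ghost_model <- function() {
  m <- get_toy()$model
  m$rxns <- rbind(m$rxns, data.frame(
    id = "GHOST", name = "ATP from nothing", lb = -1000, ub = 1000,
    gpr = NA_character_, subsystem = "ghost", pseudo = FALSE,
    stringsAsFactors = FALSE))
  m$stoich <- rbind(m$stoich, data.frame(
    rxn = "GHOST", met = c("adp_c", "pi_c", "h_c", "atp_c", "h2o_c"),
    coef = c(-1, -1, -1, 1, 1), stringsAsFactors = FALSE))
  validate_gem(m)
}

test_that("an injected ATP-generating cycle is detected with its support", {
  rep <- detect_energy_cycles(ghost_model())
  expect_false(rep$pass)
  atp <- rep$maxima[rep$maxima$carrier == "atp", ]
  expect_gt(atp$max_flux, 1e-6)
  expect_true("GHOST" %in% rep$supports$atp)
})

test_that("removing the reported support eliminates the detection", {
  m <- ghost_model()
  rep <- detect_energy_cycles(m)
  m2 <- set_bounds(m, "GHOST", lb = 0, ub = 0)
  rep2 <- detect_energy_cycles(m2)
  expect_true(rep2$pass)
})

test_that("removing reactions never creates a cycle (anti-monotone)", {
  tg <- get_toy()
  cls <- classify_reactions(tg$model)$category
  metabolic <- names(cls)[cls == "metabolic"]
  set.seed(9)
  for (drop in sample(metabolic, 4)) {
    m <- set_bounds(tg$model, drop, lb = 0, ub = 0)
    expect_true(detect_energy_cycles(m)$pass)
  }
})
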