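test_that("formula parsing handles counts, two-letter symbols and errors", {
  expect_equal(parse_formula("C6H12O6"), c(C = 6, H = 12, O = 6))
  expect_equal(parse_formula("NH4Cl"), c(N = 1, H = 4, Cl = 1))
  expect_equal(parse_formula("H"), c(H = 1))
  expect_equal(parse_formula("C37H62N7O17P3S"),
               c(C = 37, H = 62, N = 7, O = 17, P = 3, S = 1))
  expect_error(parse_formula(""), "empty")
  expect_error(molecular_weight("C6Xq2"), "unknown element")
})

test_that("molecular weights match atomic-mass table sums", {
  # frozen sums over the IUPAC-2021 table used by the package
  expect_equal(molecular_weight("C3H8O3"), 92.094, tolerance = 1e-6)   # glycerol
  expect_equal(molecular_weight("H"), 1.008)
  expect_equal(molecular_weight("C6H12O6"), 180.156, tolerance = 1e-6) # glucose
  expect_equal(molecular_weight("NH4Cl"), 53.489, tolerance = 1e-6)
  expect_equal(molecular_weight("C6H12O6", "g/mmol"),
               molecular_weight("C6H12O6") / 1000)
})

test_that("molecular weight is additive over concatenated formulas", {
  set.seed(11)
  syms <- c("C", "H", "N", "O", "P", "S")
  for (i in 1:20) {
    f1 <- paste0(sample(syms, 3), sample(1:9, 3), collapse = "")
    f2 <- paste0(sample(syms, 2), sample(1:9, 2), collapse = "")
    expect_equal(molecular_weight(paste0(f1, f2)),
                 molecular_weight(f1) + molecular_weight(f2),
                 tolerance = 1e-12)
  }
})
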