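test_that("molecular weight matches the reference value and is additive", {
  expect_equal(molecular_weight(nc_cv), 2186.56, tolerance = 0.10 / 2186.56)

  m <- residue_masses()
  expect_equal(molecular_weight("G"), m$residue_mass[["G"]] + m$water_mass)
  expect_equal(molecular_weight("GG"),
               2 * molecular_weight("G") - m$water_mass)

  set.seed(11)
  for (i in 1:20) {
    a <- random_peptide(); b <- random_peptide()
    expect_equal(molecular_weight(paste0(a, b)),
                 molecular_weight(a) + molecular_weight(b) - m$water_mass,
                 tolerance = 1e-9)
  }
})

test_that("invalid sequences are rejected with the offending position", {
  expect_error(molecular_weight(""), "empty")
  expect_error(molecular_weight("ACDX"), "position 4")
  expect_error(molecular_weight("acd"), "position 1")
  expect_error(charge_at_ph("ACB"), "position 3")
})

test_that("net charge at pH 7 reproduces reference one-decimal values", {
  expect_equal(round_half_up(charge_at_ph(table_peptides[["Pep3"]], 7), 1),
               1.7)
  expect_equal(format_charge(charge_at_ph(nc_cv, 7)), "+5")
  # only the two termini, nearly cancelling
  expect_lt(abs(charge_at_ph("GGGG", 7)), 0.15)
})

test_that("charge is strictly decreasing in pH", {
  expect_error(charge_at_ph(nc_cv, 0), "pH")
  expect_error(charge_at_ph(nc_cv, 14.5), "pH")
  grid <- seq(0.5, 13.5, by = 0.25)
  set.seed(21)
  for (i in 1:25) {
    z <- charge_at_ph(random_peptide(), grid)
    expect_true(all(diff(z) < 0))
  }
})

test_that("isoelectric point is the charge root and matches a grid oracle", {
  expect_equal(isoelectric_point(nc_cv), 10.22, tolerance = 0.3 / 10.22)
  expect_lt(abs(charge_at_ph(nc_cv, isoelectric_point(nc_cv))), 1e-6)
  expect_lt(isoelectric_point("DDDD"), 5.0)
  set.seed(31)
  for (i in 1:25) {
    s <- random_peptide()
    expect_equal(isoelectric_point(s), grid_pi(s), tolerance = 0.01,
                 label = s)
  }
})

test_that("hydrophobic moment matches the direct complex-sum oracle", {
  zero_scale <- hydrophobicity_scale()
  zero_scale$values[] <- 0
  expect_identical(hydrophobic_moment(nc_cv, zero_scale), 0)

  sc <- hydrophobicity_scale()
  expect_equal(hydrophobic_moment("W", sc), abs(sc$values[["W"]]))

  expect_equal(hydrophobic_moment(nc_cv), direct_moment(nc_cv),
               tolerance = 1e-9)
  set.seed(41)
  for (i in 1:25) {
    s <- random_peptide()
    expect_equal(hydrophobic_moment(s), direct_moment(s), tolerance = 1e-9,
                 label = s)
    expect_gte(hydrophobic_moment(s), 0)
  }
})

test_that("solubility surrogate classifies by charge magnitude", {
  expect_identical(classify_solubility(nc_cv), "Good")
  expect_identical(classify_solubility("GGGG"), "Poor")
  expect_identical(classify_solubility("KKKKKKK"), "Good")
  expect_identical(classify_solubility("DDDDDDD"), "Good")  # anionic counts too
})

test_that("the HDP physicochemistry gate flags each criterion separately", {
  prof <- physchem_profile(c(nc = nc_cv, weak = "GGGGGG"))
  out <- hdp_physchem_filter(prof)
  expect_true(out$hdp_pass[out$id == "nc"])
  expect_false(out$hdp_pass[out$id == "weak"])
  expect_false(out$charge_ok[out$id == "weak"])

  strict <- hdp_physchem_filter(prof, min_charge = 2, min_moment = 10)
  expect_false(any(strict$hdp_pass))
  expect_true(all(strict$charge_ok == out$charge_ok))

  vacuous <- hdp_physchem_filter(prof, min_charge = -99, min_moment = 0)
  expect_true(all(vacuous$hdp_pass))
})

test_that("descriptor tables are configurable from key-value files", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("K\t10.0", "NTERM\t8.5"), f)
  pk <- pka_table(f)
  expect_equal(pk$side_chain[["K"]], 10.0)
  expect_equal(pk$nterm, 8.5)
  # lowering the Lys pKa lowers the pI of a Lys-rich peptide
  expect_lt(isoelectric_point("KKKAAK", pk), isoelectric_point("KKKAAK"))

  f2 <- tempfile(fileext = ".tsv")
  writeLines("G\t-1", f2)
  expect_error(residue_masses(f2), "positive")

  # the shipped editable tables reproduce the built-in defaults
  ext <- function(nm) system.file("extdata", nm, package = "hdpminer")
  expect_identical(pka_table(ext("pka_calibrated.tsv"))$side_chain,
                   pka_table()$side_chain)
  expect_identical(residue_masses(ext("residue_masses.tsv"))$residue_mass,
                   residue_masses()$residue_mass)
  expect_identical(hydrophobicity_scale(ext("eisenberg_scale.tsv"))$values,
                   hydrophobicity_scale()$values)
})
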