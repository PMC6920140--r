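test_that("disulfide-aware composition matches residue summation", {
  cases <- list(
    list(seq = HEP_SEQ, ss = 4),
    list(seq = "G", ss = 0),
    list(seq = REC_SEQ, ss = 4),
    list(seq = "ACDEFGHIKLMNPQRSTVWY", ss = 0),
    list(seq = "CCCC", ss = 2)
  )
  for (cs in cases) {
    got <- composition_of(peptide(cs$seq, cs$ss))
    want <- oracle_peptide_formula(cs$seq, cs$ss)
    expect_identical(unclass(got)[names(want)],
                     stats::setNames(as.integer(want), names(want)),
                     label = cs$seq)
    expect_setequal(names(got), names(want))
  }
  expect_identical(format(composition_of(peptide(HEP_SEQ, 4))),
                   "C117H172N32O31S8")
  expect_identical(format(composition_of("G")), "C2H5N1O2")
})

test_that("invalid sequences and impossible disulfide counts error", {
  expect_error(peptide("DTHZ"), "invalid residue")
  expect_error(peptide(""), "empty")
  expect_error(peptide("GAG", n_disulfides = 1), "cysteine")
  expect_error(peptide(HEP_SEQ, n_disulfides = 5), "cysteine")
})

test_that("composition arithmetic is element-wise and guards underflow", {
  a <- elemental_composition(c(C = 2, H = 6))
  b <- elemental_composition(c(H = 2, O = 1))
  expect_identical(format(a + b), "C2H8O1")
  expect_identical(format((a + b) - b), "C2H6")
  expect_error(a - b, "below zero")
  expect_error(elemental_composition(c(C = -1)), "non-negative")
})

test_that("monoisotopic masses reproduce reference values", {
  expect_equal(monoisotopic_mass(elemental_composition(c(H = 2, O = 1))),
               18.01056, tolerance = 1e-5)
  M <- monoisotopic_mass(composition_of(peptide(HEP_SEQ, 4)))
  expect_lt(abs(M - 2777.06218), 0.005)
  Mrec <- monoisotopic_mass(composition_of(peptide(REC_SEQ, 4)))
  expect_equal(round(Mrec), 2715)
  # oracle residue-mass sum agrees to the oracle's 5-decimal precision
  expect_equal(M, sum(ORACLE_RESIDUE_MASS[strsplit(HEP_SEQ, "")[[1]]]) +
                 ORACLE_WATER - 8 * ORACLE_H, tolerance = 1e-3)
  expect_error(monoisotopic_mass(elemental_composition(c(Zz = 1))), "Zz")
})

test_that("charge-state algebra matches the observed ion series", {
  M <- monoisotopic_mass(composition_of(peptide(HEP_SEQ, 4)))
  for (i in seq_len(nrow(OBSERVED_MZ))) {
    th <- mz_of(M, OBSERVED_MZ$z[i])
    expect_lt(abs(th - OBSERVED_MZ$mz[i]) / OBSERVED_MZ$mz[i] * 1e6, 2)
  }
  expect_equal(mz_of(1000, 1), 1000 + 1.007276, tolerance = 1e-5)
  expect_equal(neutral_mass_from_mz(556.420376, 5), 2777.066, tolerance = 2e-3)
  expect_equal(neutral_mass_from_mz(926.695333, 3), 2777.064, tolerance = 2e-3)
  expect_error(mz_of(1000, 0))
  expect_error(neutral_mass_from_mz(0.5, 1))
})

test_that("m/z round-trip is exact and mass is additive", {
  set.seed(42)
  M <- runif(50, 500, 5000)
  for (z in 1:6) {
    expect_lt(max(abs(neutral_mass_from_mz(mz_of(M, z), z) - M)), 1e-9)
  }
  a <- elemental_composition(c(C = 3, H = 5, N = 1, O = 1, S = 1))
  b <- elemental_composition(c(C = 9, H = 9, N = 1, O = 1))
  expect_equal(monoisotopic_mass(a + b),
               monoisotopic_mass(a) + monoisotopic_mass(b), tolerance = 1e-12)
})

test_that("each disulfide bridge removes exactly two hydrogens", {
  for (ss in 0:4) {
    with_ss <- unclass(composition_of(peptide(HEP_SEQ, ss)))
    no_ss <- unclass(composition_of(peptide(HEP_SEQ, 0)))
    expect_identical(no_ss["H"] - with_ss["H"], c(H = 2L * ss))
    expect_identical(with_ss[names(with_ss) != "H"],
                     no_ss[names(no_ss) != "H"])
  }
})

test_that("F21/R24 vs L21/K24 mass gap equals the residue substitutions", {
  M_fr <- monoisotopic_mass(composition_of(peptide(HEP_SEQ, 4)))
  M_lk <- monoisotopic_mass(composition_of(peptide(REC_SEQ, 4)))
  gap <- (ORACLE_RESIDUE_MASS["F"] - ORACLE_RESIDUE_MASS["L"]) +
    (ORACLE_RESIDUE_MASS["R"] - ORACLE_RESIDUE_MASS["K"])
  expect_equal(M_fr - M_lk, unname(gap), tolerance = 1e-3)
  expect_equal(M_fr - M_lk, 61.99, tolerance = 0.01)
})

test_that("constants table is complete and physically sane", {
  tab <- amino_acid_table()
  expect_setequal(names(tab$residue_formulas),
                  strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  for (f in tab$residue_formulas) {
    expect_gte(unclass(f)["C"], 1)
    expect_gte(unclass(f)["N"], 1)
  }
  expect_identical(format(tab$water), "H2O1")
  expect_gt(tab$proton_mass, 1.00727)
  expect_lt(tab$proton_mass, 1.00728)
  expect_equal(tab$legacy_hydrogen, 1.00794)
})

test_that("peptides load from single-record FASTA", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">hep", HEP_SEQ), fa)
  p <- peptide(fa, n_disulfides = 4)
  expect_identical(p$sequence, HEP_SEQ)
})
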