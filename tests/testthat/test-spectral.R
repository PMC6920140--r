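test_that("single-atom isotope patterns equal the element table", {
  p <- isotope_pattern(elemental_composition(c(C = 1)))
  expect_equal(p$mz, c(12.0, 13.00335), tolerance = 1e-5)
  expect_equal(p$abundance, c(0.9893, 0.0107), tolerance = 1e-9)
})

test_that("isotope patterns match the full-enumeration oracle", {
  formulas <- list(c(C = 2, H = 5, N = 1, O = 2),  # glycine, 10 atoms
                   c(H = 2, O = 1),
                   c(C = 1, H = 4, S = 1),
                   c(C = 3, H = 5, N = 1, O = 1, S = 1))
  for (f in formulas) {
    got <- isotope_pattern(elemental_composition(f), abundance_floor = 0)
    want <- oracle_isotope_pattern(f, n_keep = 8)
    k <- min(nrow(got), nrow(want))
    expect_lt(max(abs(got$abundance[1:k] - want$abundance[1:k])), 1e-6)
    expect_lt(max(abs(got$mz[1:k] - want$mass[1:k])), 1e-6)
  }
})

test_that("isotope patterns normalize, start at the monoisotopic mass, and shift right for large peptides", {
  comp <- composition_of(peptide(HEP_SEQ, 4))
  for (z in c(0, 3, 5)) {
    p <- isotope_pattern(comp, z = z)
    expect_equal(sum(p$abundance), 1, tolerance = 1e-9)
    expect_true(all(diff(p$mz) > 0))
  }
  p0 <- isotope_pattern(comp)
  expect_equal(p0$mz[1], monoisotopic_mass(comp), tolerance = 1e-9)
  # most abundant isotopologue of a ~2.8 kDa peptide is not the monoisotopic
  expect_gt(which.max(p0$abundance), 1)
  p5 <- isotope_pattern(comp, z = 5)
  expect_equal(p5$mz[1], mz_of(monoisotopic_mass(comp), 5), tolerance = 1e-9)
  spacing <- diff(p5$mz)
  expect_true(all(abs(spacing - 1.00335 / 5) < 0.01))
})

test_that("pattern of a sum composition equals the convolution of patterns", {
  a <- c(C = 2, H = 3, N = 1, O = 1)
  b <- c(C = 3, H = 5, N = 1, O = 1, S = 1)
  pa <- isotope_pattern(elemental_composition(a), abundance_floor = 0)
  pb <- isotope_pattern(elemental_composition(b), abundance_floor = 0)
  pab <- isotope_pattern(elemental_composition(a) + elemental_composition(b),
                         abundance_floor = 0)
  # discrete convolution of the two abundance vectors on the nucleon grid
  conv <- rep(0, nrow(pa) + nrow(pb) - 1)
  for (i in seq_len(nrow(pa))) {
    for (j in seq_len(nrow(pb))) {
      conv[i + j - 1] <- conv[i + j - 1] + pa$abundance[i] * pb$abundance[j]
    }
  }
  k <- min(nrow(pab), length(conv))
  expect_lt(max(abs(pab$abundance[1:k] - conv[1:k])), 1e-6)
})

test_that("envelope similarity: identity scores 1, shifted peaks score 0", {
  comp <- composition_of(peptide(HEP_SEQ, 4))
  pat <- isotope_pattern(comp, z = 5)
  self <- envelope_similarity(pat, mass_spectrum(pat$mz, pat$abundance))
  expect_equal(self$similarity, 1, tolerance = 1e-12)
  expect_true(all(abs(self$ppm_errors) < 1e-9))
  shifted <- mass_spectrum(pat$mz * (1 + 10e-6), pat$abundance)
  expect_equal(envelope_similarity(pat, shifted, match_tol_ppm = 5)$similarity, 0)
})

test_that("envelope similarity stays high under 5% intensity noise", {
  comp <- composition_of(peptide(HEP_SEQ, 4))
  pat <- isotope_pattern(comp, z = 5)
  for (seed in 1:20) {
    sim <- simulate_precursor_spectrum(charges = 5L, intensity_cv = 0.05,
                                       jitter_ppm = 2, seed = seed)
    res <- envelope_similarity(pat, sim$spectrum, match_tol_ppm = 10)
    expect_gt(res$similarity, 0.95)
  }
})

test_that("deconvolution recovers the printed 2,777 Da series", {
  d <- deconvolute(OBSERVED_MZ)
  expect_equal(round(d$inferred_neutral_mass), 2777)
  expect_lt(d$ppm_spread, 5)
  expect_true(d$consistent)
})

test_that("deconvolution is exact on noiseless series and flags inconsistency", {
  M <- 2777.0632
  single <- deconvolute(data.frame(mz = mz_of(M, 4), z = 4))
  expect_equal(single$inferred_neutral_mass, M, tolerance = 1e-9)
  expect_equal(single$ppm_spread, 0)
  series <- deconvolute(data.frame(mz = mz_of(M, c(5, 4, 3)), z = c(5, 4, 3)))
  expect_lt(abs(series$inferred_neutral_mass - M), 1e-6)
  bad <- deconvolute(data.frame(mz = c(mz_of(M, 5), mz_of(M * 1.0001, 4)),
                                z = c(5, 4)))
  expect_false(bad$consistent)
  expect_error(deconvolute(data.frame(mz = c(500, 600), z = c(3, 3))),
               "distinct")
})

test_that("deconvolution of jittered synthetic series recovers mass within 2 ppm", {
  for (seed in 1:10) {
    sim <- simulate_precursor_spectrum(jitter_ppm = 2, intensity_cv = 0,
                                       seed = seed)
    obs <- data.frame(mz = sim$truth$envelopes *
                        (1 + runif(3, -2, 2) * 1e-6),
                      z = sim$truth$charges)
    d <- deconvolute(obs)
    expect_lt(abs(d$inferred_neutral_mass - sim$truth$mass) /
                sim$truth$mass * 1e6, 2)
  }
})

test_that("charge assignment recognises envelopes by isotope spacing", {
  sim5 <- simulate_precursor_spectrum(charges = 5L, jitter_ppm = 0,
                                      intensity_cv = 0, seed = 1)
  got5 <- assign_charges(sim5$spectrum)
  expect_equal(got5$z, 5L)
  expect_equal(got5$mz, sim5$truth$envelopes[["5"]], tolerance = 1e-6)
  sim1 <- simulate_precursor_spectrum(charges = 1L, jitter_ppm = 0,
                                      intensity_cv = 0, seed = 1)
  expect_equal(assign_charges(sim1$spectrum)$z, 1L)
})

test_that("charge assignment survives a co-eluting contaminant", {
  for (seed in 1:10) {
    sim <- simulate_precursor_spectrum(contaminant = TRUE,
                                       contaminant_rel = 0.4, seed = seed)
    got <- assign_charges(sim$spectrum)
    expect_setequal(got$z, c(5L, 4L, 3L))
  }
})
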