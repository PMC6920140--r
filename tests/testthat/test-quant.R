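test_that("feature alignment honours both tolerances", {
  one <- data.frame(mz = c(556.42, 700.10), rt = c(3.00, 4.00), area = c(10, 5))
  same3 <- list(s1 = one, s2 = one, s3 = one)
  al <- align_features(same3)
  expect_equal(length(unique(al$feature)), 2)
  expect_true(all(table(al$feature) == 3))
  # +0.2 min shift exceeds the 0.10 min tolerance: distinct features
  shifted <- list(a = one, b = transform(one, rt = rt + 0.2))
  expect_equal(length(unique(align_features(shifted)$feature)), 4)
  # within-tolerance jitter across a 117-sample sequence: one feature per analyte
  set.seed(5)
  seq117 <- lapply(1:117, function(i) {
    data.frame(mz = c(556.42, 700.10) + runif(2, -0.02, 0.02),
               rt = c(3.00, 4.00) + runif(2, -0.04, 0.04),
               area = c(10, 5) * exp(rnorm(2, 0, 0.14)))
  })
  al117 <- align_features(seq117)
  expect_equal(length(unique(al117$feature)), 2)
})

test_that("%RSD matches its definition and is scale invariant", {
  expect_equal(percent_rsd(c(5, 5, 5)), 0)
  expect_equal(percent_rsd(c(1, 2, 3)), 50)
  set.seed(2)
  x <- rlnorm(117, 0, 0.14)
  expect_equal(percent_rsd(3.7 * x), percent_rsd(x), tolerance = 1e-12)
  expect_error(percent_rsd(c(1)), "at least 2")
  expect_error(percent_rsd(c(-1, 1)), "mean is zero")
  # IS areas drawn at CV 14%, n = 117: %RSD lands in [10, 18] across seeds
  rsds <- vapply(1:20, function(seed) {
    percent_rsd(simulate_quant_study(seed = seed)$is_areas)
  }, numeric(1))
  expect_true(all(rsds >= 10 & rsds <= 18))
})

test_that("calibration fit and quantitation invert each other", {
  cal <- fit_calibration(1:8, 2 * (1:8) + 1)
  expect_equal(cal$slope, 2, tolerance = 1e-12)
  expect_equal(cal$intercept, 1, tolerance = 1e-12)
  expect_equal(cal$r_squared, 1, tolerance = 1e-12)
  mid <- 2 * 4.5 + 1
  q <- quantify(cal, mid)
  expect_equal(q$concentration, 4.5, tolerance = 1e-12)
  expect_true(q$in_range)
  expect_false(quantify(cal, 2 * 100 + 1)$in_range)
  expect_false(quantify(cal, 0)$in_range)
  expect_error(fit_calibration(rep(3, 4), 1:4), "identical")
  expect_error(quantify(fit_calibration(c(1, 2), c(5, 5)), 1), "slope")
})

test_that("the 8-point 0.6-75 nM design recovers slope and spike within 10%", {
  for (seed in 1:10) {
    st <- simulate_quant_study(seed = seed)
    cal <- fit_calibration(st$calibration$nM, st$calibration$response)
    expect_lt(abs(cal$slope - st$truth$response_per_nM) /
                st$truth$response_per_nM, 0.10)
    est <- mean(quantify(cal, st$spike_responses)$concentration)
    expect_lt(abs(est - st$truth$spike_nM) / st$truth$spike_nM, 0.10)
  }
})

test_that("friedman statistic and p agree with stats::friedman.test", {
  set.seed(8)
  for (i in 1:10) {
    m <- matrix(rnorm(40), 10, 4)
    ours <- friedman_test(m)
    ref <- stats::friedman.test(m)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
  # with ties (mid-ranks + tie correction)
  mt <- matrix(c(1, 1, 2, 3, 2, 2, 1, 1, 3, 4, 5, 5), 3, 4, byrow = TRUE)
  expect_equal(friedman_test(mt)$statistic,
               unname(stats::friedman.test(mt)$statistic), tolerance = 1e-12)
})

test_that("degenerate and extreme friedman inputs behave as documented", {
  flat <- friedman_test(matrix(5, 4, 3))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  # strictly increasing rows maximise the statistic at n(k-1)
  set.seed(1)
  inc <- t(apply(matrix(rnorm(20), 5, 4), 1, sort))
  f <- friedman_test(inc)
  expect_equal(f$statistic, 5 * (4 - 1), tolerance = 1e-12)
  expect_error(friedman_test(matrix(c(1, NA, 2, 3), 2, 2)), "incomplete")
  expect_error(friedman_test(matrix(1, 1, 3)), ">= 2")
})

test_that("exact enumeration matches the independent permutation oracle", {
  set.seed(13)
  for (i in 1:3) {
    m <- matrix(rnorm(12), 4, 3)
    ours <- friedman_test(m, exact = TRUE)
    orc <- oracle_friedman_exact(m)
    expect_equal(ours$statistic, orc$statistic, tolerance = 1e-12)
    expect_equal(ours$p_value, orc$p, tolerance = 1e-12)
  }
})

test_that("friedman is invariant under monotone within-subject transforms", {
  set.seed(17)
  m <- matrix(rlnorm(40), 10, 4)
  base <- friedman_test(m)
  for (f in list(log, sqrt, function(x) x^3, function(x) 5 * x + 2)) {
    tr <- friedman_test(f(m))
    expect_equal(tr$statistic, base$statistic, tolerance = 1e-12)
    expect_equal(tr$p_value, base$p_value, tolerance = 1e-12)
  }
})

test_that("rising-hepcidin time-courses are detected at the default effect size", {
  detected <- vapply(1:20, function(seed) {
    st <- simulate_quant_study(seed = seed)
    timecourse_test(st$hepcidin)$friedman$p_value < 0.05
  }, logical(1))
  expect_gte(mean(detected), 0.9)
})

test_that("timecourse summary reports medians and quartiles per timepoint", {
  st <- simulate_quant_study(seed = 4)
  tc <- timecourse_test(st$iron, timepoints = c(0, 2, 4, 6))
  expect_identical(tc$summary$timepoint, c(0, 2, 4, 6))
  expect_equal(tc$summary$median,
               unname(apply(st$iron, 2, median)), tolerance = 1e-12)
  expect_true(all(tc$summary$q1 <= tc$summary$median))
  expect_true(all(tc$summary$median <= tc$summary$q3))
})
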