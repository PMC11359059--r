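test_that("the low-pass filter passes DC unchanged and validates its inputs", {
  x <- rep(3.7, 100)
  expect_equal(lowpassFilter(x, 60, filterSpec(cutoff_hz = 10)), x,
               tolerance = 1e-8)
  expect_error(lowpassFilter(x, 60, filterSpec(cutoff_hz = 30)),
               class = "psafl_config_error")
  expect_error(lowpassFilter(x[1:4], 60, filterSpec(order = 2, cutoff_hz = 10)),
               class = "psafl_input_error")
  expect_length(lowpassFilter(sin(1:100), 60, filterSpec(cutoff_hz = 10)), 100)
})

test_that("stopband attenuation matches the squared second-order response", {
  fs <- 60
  t <- (0:599) / fs
  x <- sin(2 * pi * 25 * t)
  y <- lowpassFilter(x, fs, filterSpec(order = 2, cutoff_hz = 10))
  # analytic: |H| = 1/sqrt(1 + (25/10)^4) = 0.158 per pass, squared ~ 0.025
  expect_lt(sqrt(mean(y^2)) / sqrt(mean(x^2)), 0.05)
})

test_that("acceleration by second differences is exact on polynomials", {
  fs <- 50
  t <- (0:99) / fs
  ramp <- 3 * t + 2
  a <- deriveAcceleration(ramp, fs)
  expect_equal(max(abs(a[2:99])), 0, tolerance = 1e-9)
  quad <- t^2
  a2 <- deriveAcceleration(quad, fs)
  expect_equal(a2[2:99], rep(2, 98), tolerance = 1e-7)
  # endpoints: one-sided second differences, exact for quadratics too
  expect_equal(a2[1], 2, tolerance = 1e-7)
  expect_equal(a2[100], 2, tolerance = 1e-7)
  expect_error(deriveAcceleration(c(1, 2), fs), class = "psafl_input_error")
})

test_that("acceleration of a sinusoid approaches its analytic second derivative", {
  f <- 1; fs <- 40 * f
  t <- (0:199) / fs
  x <- sin(2 * pi * f * t)
  a <- deriveAcceleration(x, fs)
  expected <- -(2 * pi * f)^2 * x
  interior <- 2:199
  expect_lt(max(abs(a[interior] - expected[interior])) / (2 * pi * f)^2, 0.01)
})

test_that("acceleration works column-wise on matrices", {
  fs <- 10
  m <- cbind(a = (0:20 / fs)^2, b = 5 * (0:20 / fs))
  acc <- deriveAcceleration(m, fs)
  expect_equal(dim(acc), dim(m))
  expect_equal(acc[5, "a"], 2, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(acc[5, "b"], 0, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("trunk displacement reproduces the hand-computed baseline example", {
  p <- rbind(matrix(rep(c(1, 2, 3), each = 10), nrow = 10), c(2, 4, 6))
  td <- trunkDisplacement(p, baseline_n = 10)
  expect_equal(td$td, 6)                       # |2-1| + |4-2| + |6-3|
  expect_equal(unname(td$components[1, ]), c(1, 2, 3))
  expect_equal(td$mean_td, 6)
})

test_that("trunk displacement is zero for constant input and averages markers", {
  p0 <- matrix(5, 15, 3)
  expect_equal(trunkDisplacement(p0)$td, rep(0, 5))
  # markers with constant per-step TD 2 and 4 average to 3
  m1 <- rbind(matrix(0, 10, 3), matrix(c(2, 0, 0), 4, 3, byrow = TRUE))
  m2 <- rbind(matrix(0, 10, 3), matrix(c(4, 0, 0), 4, 3, byrow = TRUE))
  expect_equal(trunkDisplacement(list(m1, m2))$td, rep(3, 4))
})

test_that("trunk displacement is translation-invariant and guards short input", {
  set.seed(5)
  p <- matrix(rnorm(45), 15, 3)
  shifted <- sweep(p, 2, c(10, -4, 2.5), `+`)
  expect_equal(trunkDisplacement(p)$td, trunkDisplacement(shifted)$td,
               tolerance = 1e-12)
  expect_error(trunkDisplacement(p[1:10, ]), class = "psafl_input_error")
})

test_that("feature dimensionality is channels x 3 x n_bins", {
  # 5 channels x 3 axes x 1 bin = 15 features; 9 channels give 27
  f5 <- frequencyFeatures(flatTrials(3, 5, value = 1), n_bins = 1,
                          scale = "none")
  expect_equal(ncol(featureValues(f5)), 15)
  f9 <- frequencyFeatures(flatTrials(3, 9, value = 1), n_bins = 1,
                          scale = "none")
  expect_equal(ncol(featureValues(f9)), 27)
  cohort <- generateCohort(tinyCohortConfig(n_per_group = 2))
  fm <- frequencyFeatures(cohort, n_bins = 4)
  expect_equal(dim(featureValues(fm)), c(6, 5 * 3 * 4))
  expect_identical(rowIds(fm), sort(cohortSubjects(cohort)$subject_id))
})

test_that("a constant-position trial has zero energy beyond DC", {
  fm <- frequencyFeatures(flatTrials(2, 2, value = 4), n_bins = 5,
                          scale = "none")
  v <- featureValues(fm)
  non_dc <- !grepl("bin1$", colnames(v))
  expect_equal(max(abs(v[, non_dc])), 0, tolerance = 1e-10)
})

test_that("mixed sampling rates and oversized n_bins are rejected", {
  trials <- c(flatTrials(1, 2, fs = 60), flatTrials(1, 2, fs = 200))
  expect_error(frequencyFeatures(trials, n_bins = 2),
               class = "psafl_input_error")
  expect_error(frequencyFeatures(flatTrials(2, 2, n_samples = 12), n_bins = 8),
               class = "psafl_input_error")
})

test_that("features ignore a weak tone far above the cutoff", {
  cfg <- tinyCohortConfig(n_per_group = 3, noise_sd = 0, seed = 9)
  cohort <- generateCohort(cfg)
  contaminated <- cohortTrials(cohort)
  fs <- cfg$sampling_rate_hz
  contaminated <- lapply(contaminated, function(tr) {
    n <- nrow(tr@positions)
    tone <- 0.05 * sin(2 * pi * 25 * (0:(n - 1)) / fs)
    tr@positions <- tr@positions + tone
    tr
  })
  f_clean <- featureValues(frequencyFeatures(cohortTrials(cohort), n_bins = 4))
  f_tone <- featureValues(frequencyFeatures(contaminated, n_bins = 4))
  expect_lt(max(abs(f_clean - f_tone)), 0.01)
})

test_that("subject averaging pools each subject's trials", {
  cfg <- tinyCohortConfig(n_per_group = 2)
  cfg2 <- cohortConfig(n_subjects_per_group = 2, n_tasks = 2,
                       n_repetitions = 3, duration_s = 2,
                       trunk_amplitude_per_group = c(1, 2, 4), seed = 7)
  cohort <- generateCohort(cfg2)
  fm <- frequencyFeatures(cohort, n_bins = 3)
  expect_equal(nrow(featureValues(fm)), 6)  # one row per subject, not per trial
})
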