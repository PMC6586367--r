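# module tests use a coarse grid (df = 0.002, f <= 1.024) for speed; the
# acceptance suite exercises the production grid (df = 0.001)

test_that("solver finds the zero solution below threshold, nonzero above", {
  m <- resonant_model()
  gc_ <- critical_coupling(m)
  below <- solve_dmft(m, 0.9 * gc_, config = fast_config())
  expect_true(below$zero_solution)
  expect_lte(max(below$spectrum_x$values), 1e-8)
  above <- solve_dmft(m, 1.3 * gc_, config = fast_config())
  expect_false(above$zero_solution)
  expect_true(above$converged)
  expect_gt(solution_variance(above), 0)
})

test_that("resonant solutions peak at f_0, non-resonant at zero", {
  m <- resonant_model()
  sol <- solve_dmft(m, 2 * critical_coupling(m), config = fast_config())
  f <- spectrum_frequencies(sol$spectrum_x)
  fp <- f[which.max(sol$spectrum_x$values)]
  expect_lt(abs(fp - resonance_frequency(0.25, 1)), 2 * 0.002)
  m2 <- nonresonant_model()
  sol2 <- solve_dmft(m2, 2 * critical_coupling(m2), config = fast_config())
  f2 <- spectrum_frequencies(sol2$spectrum_x)
  expect_equal(f2[which.max(sol2$spectrum_x$values)], 0)
})

test_that("converged solutions satisfy the fixed-point relation", {
  m <- resonant_model()
  g <- 2 * critical_coupling(m)
  cfg <- fast_config()
  sol <- solve_dmft(m, g, config = cfg)
  G <- sol$gain
  renew <- G * g^2 * sol$spectrum_rate$values
  res <- sum(abs(renew - sol$spectrum_x$values)) / sum(sol$spectrum_x$values)
  expect_lt(res, 10 * cfg$tolerance)
})

test_that("the fixed point does not depend on the initial level", {
  # the white initial spectrum's level is arbitrary; the solution is not
  m <- resonant_model()
  g <- 2 * critical_coupling(m)
  sol1 <- solve_dmft(m, g, config = fast_config(init_variance = 0.01))
  sol2 <- solve_dmft(m, g, config = fast_config(init_variance = 100))
  expect_lt(spectrum_distance(sol1$spectrum_x, sol2$spectrum_x), 1e-3)
  expect_equal(solution_variance(sol1), solution_variance(sol2),
               tolerance = 1e-4)
})

test_that("solver runs on the published 3- and 4-dimensional models", {
  for (A in list(table_matrix_3d(), table_matrix_4d())) {
    m <- general_model(A)
    gc_ <- critical_coupling(m)
    sol <- solve_dmft(m, 1.5 * gc_, config = fast_config())
    expect_false(sol$zero_solution)
    f <- spectrum_frequencies(sol$spectrum_x)
    fp <- f[which.max(sol$spectrum_x$values)]
    argmax <- ratechaos:::max_gain(m)$argmax
    expect_lt(abs(fp - argmax), 0.02)
  }
})

test_that("solution variance accounting is consistent", {
  m <- resonant_model()
  sol <- solve_dmft(m, 2 * critical_coupling(m), config = fast_config())
  expect_equal(solution_variance(sol), spectrum_variance(sol$spectrum_x))
})

test_that("sharpening: early iterates follow powers of the normalized gain", {
  m <- resonant_model()
  g <- 2 * critical_coupling(m)
  sh <- sharpening_iterates(m, g, n_iterations = 3, config = fast_config())
  # iteration 1 is exactly proportional to the gain
  expect_equal(sh$iterates[, 1], sh$gain_normalized, tolerance = 1e-10)
  # half-maximum width decreases over iterations
  width <- function(v) {
    i <- which.max(v); half <- v[i] / 2
    sum(v > half)
  }
  w <- apply(sh$iterates, 2, width)
  expect_true(all(diff(w) < 0))
  # predictions sharpen identically in ordering
  wp <- apply(sh$predictions, 2, width)
  expect_true(all(diff(wp) < 0))
})

test_that("heterogeneous effective gain reduces to the homogeneous one", {
  f <- seq(0, 1, by = 0.01)
  G <- ratechaos:::gain_adaptation(0.25, 1, f)
  expect_equal(heterogeneous_gain(0.25, 1, 0, f), G, tolerance = 1e-14)
  GH <- heterogeneous_gain(0.25, 1, 0.5, f)
  # zero-frequency enhancement: G_H(0) = G(0)/(1 - sigma^2 G(0)) > G(0)
  expect_equal(GH[1], G[1] / (1 - 0.5^2 * G[1]), tolerance = 1e-12)
  expect_true(all(GH >= G - 1e-15))
  # overly strong heterogeneity invalidates the filter
  expect_error(heterogeneous_gain(0.25, 0, 3, 0), "denominator")
})

test_that("heterogeneity changes the solution only at low frequencies", {
  m <- resonant_model()
  g <- 2 * critical_coupling(m)
  cfg <- fast_config()
  hom <- solve_dmft(m, g, config = cfg)
  het <- solve_dmft_heterogeneous(0.25, 1, 0.5, g, config = cfg)
  f <- spectrum_frequencies(hom$spectrum_x)
  lo <- f <= 0.02
  hi <- f > 0.02
  rel_hi <- sum(abs(het$spectrum_x$values[hi] - hom$spectrum_x$values[hi])) /
    sum(hom$spectrum_x$values[hi])
  expect_lt(rel_hi, 0.1)
  # low-frequency power is strictly enhanced
  expect_gt(mean(het$spectrum_x$values[lo]), mean(hom$spectrum_x$values[lo]))
  # peak location unchanged within grid resolution
  expect_lt(abs(f[which.max(het$spectrum_x$values)] -
                f[which.max(hom$spectrum_x$values)]), 2 * cfg$freq_step)
})

test_that("linear response below criticality shapes signal and noise equally", {
  df <- 0.002
  n <- 513
  white <- new_spectrum(rep(0.1, n), df)
  f_I <- 0.1
  m1 <- adaptation_model(0.25, 1)
  m2 <- adaptation_model(1, 0.1)
  g1 <- 0.3 * critical_coupling(m1)
  g2 <- 0.3 * critical_coupling(m2)
  p1 <- linear_response_prediction(m1, g1, white, amplitude = 0.5, f_I = f_I)
  p2 <- linear_response_prediction(m2, g2, white, amplitude = 0.5, f_I = f_I)
  expect_equal(p1$snr, p2$snr, tolerance = 1e-12)
  expect_equal(p1$snr, 0.5^2 / (4 * 0.1 * df), tolerance = 1e-12)
  # g = 0 reduces to the single-unit gain
  p0 <- linear_response_prediction(m1, 0, white, 0.5, f_I)
  expect_equal(p0$chi2, unit_gain(m1, spectrum_frequencies(white))$gain,
               tolerance = 1e-12)
  # at criticality the pole invalidates the theory
  expect_error(linear_response_prediction(m1, critical_coupling(m1), white,
                                          0.5, f_I), "g_c")
})

test_that("driven solver reduces to the undriven one at zero amplitude", {
  m <- resonant_model()
  g <- 2 * critical_coupling(m)
  cfg <- fast_config()
  a <- solve_dmft(m, g, config = cfg)
  b <- solve_dmft_driven(m, g, amplitude = 0, f_I = 0.12, config = cfg)
  expect_equal(b$spectrum_x$values, a$spectrum_x$values)
  expect_length(b$oscillatory_peaks, 0)
})

test_that("oscillatory drive produces harmonic peaks on a chaotic background", {
  m <- resonant_model()
  g <- 2 * critical_coupling(m)
  cfg <- fast_config(tolerance = 2e-2, max_iterations = 60, seed = 5)
  cfg$n_samples <- 96L
  sol <- solve_dmft_driven(m, g, amplitude = 0.5, f_I = 0.12, config = cfg)
  b <- sol$oscillatory_peaks
  expect_gt(b[[1]], 0)
  expect_gt(b[[3]], b[[2]])     # odd harmonics dominate even ones
  expect_gt(spectrum_variance(sol$spectrum_x), 0.05)  # chaos not suppressed
  sp <- split_signal_background(sol, 0.12)
  expect_gt(sp$snr, 1)
  vd <- variance_decomposition(sol)
  expect_equal(vd$total_variance, vd$P_bkg + vd$P_osc, tolerance = 1e-12)
  expect_error(solve_dmft_driven(m, g, 0.5, f_I = 0.1205, config = cfg),
               "multiple")
})

test_that("strong drive near resonance suppresses the chaotic background", {
  # matched microscopic runs (N = 1000, A_I = 1.5, f_I at resonance) retain
  # P_bkg/P_osc ~ 0.1: suppression is strong but not total at this drive
  m <- resonant_model()
  g <- 2 * critical_coupling(m)
  undriven_var <- solution_variance(solve_dmft(m, g, config = fast_config()))
  cfg <- fast_config(tolerance = 1e-3, max_iterations = 150, seed = 5)
  cfg$n_samples <- 96L
  sol <- solve_dmft_driven(m, g, amplitude = 1.5, f_I = 0.102, config = cfg)
  vd <- variance_decomposition(sol)
  expect_lt(vd$P_bkg, 0.2 * vd$P_osc)
  expect_lt(vd$P_bkg, 0.25 * undriven_var)
})
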