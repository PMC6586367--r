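test_that("spectrum/autocorr bridge round-trips and preserves variance", {
  set.seed(3)
  for (i in 1:5) {
    v <- abs(rnorm(65))                       # M = 128
    sp <- new_spectrum(v, 0.01)
    ac <- spectrum_to_autocorr(sp)
    expect_equal(ac$values[1], spectrum_variance(sp), tolerance = 1e-12)
    back <- autocorr_to_spectrum(ac)
    expect_lt(max(abs(back$values - sp$values)) / max(sp$values), 1e-10)
  }
})

test_that("flat spectrum maps to a discrete delta at lag zero", {
  sp <- new_spectrum(rep(2, 129), 0.01)
  ac <- spectrum_to_autocorr(sp)
  expect_gt(ac$values[1], 0)
  expect_lt(max(abs(ac$values[-1])), 1e-12 * ac$values[1])
})

test_that("Lorentzian spectrum pairs with an exponential autocorrelation", {
  # S(f) = 2 a s2 / (a^2 + w^2)  <->  C(tau) = s2 exp(-a |tau|), w = 2 pi f
  a <- 1; s2 <- 1
  df <- 0.005; n_half <- 16384               # wide grid, fine bins
  f <- seq(0, by = df, length.out = n_half + 1)
  S <- 2 * a * s2 / (a^2 + (2 * pi * f)^2)
  ac <- spectrum_to_autocorr(new_spectrum(S, df))
  lags <- autocorr_lags(ac)
  # the truncated high-frequency tail shows up as a narrow spike around
  # lag zero; the decay region matches the continuous pair closely
  keep <- lags >= 0.2 & lags <= 3
  expect_lt(max(abs(ac$values[keep] - s2 * exp(-a * lags[keep]))), 1e-3)
  expect_equal(ac$values[1], s2, tolerance = 2e-3)
})

test_that("file round trip preserves spectra and autocorrelations", {
  path <- withr::local_tempfile(fileext = ".csv")
  sp <- new_spectrum(abs(rnorm(33)), 0.01)
  write_spectrum(sp, path)
  sp2 <- read_spectrum(path)
  expect_equal(sp2$values, sp$values)
  expect_equal(sp2$freq_step, sp$freq_step)
  ac <- exp_autocorr()
  write_autocorr(ac, path)
  expect_equal(read_autocorr(path)$values, ac$values)
})

test_that("clipped-linear series map: degenerate and small-variance limits", {
  z <- new_autocorr(rep(0, 33), 0.1)
  expect_equal(map_autocorr_piecewise_linear(z)$values, rep(0, 33))
  # tiny variance: clipping never reached, map is the identity
  ac <- exp_autocorr(sigma2 = 1e-4)
  out <- map_autocorr_piecewise_linear(ac)
  expect_equal(out$values, ac$values, tolerance = 1e-6)
})

test_that("clipped-linear series map matches the Monte-Carlo oracle", {
  ac <- exp_autocorr(sigma2 = 1, tau0 = 1, n_half = 16, dt = 0.25)
  out <- map_autocorr_piecewise_linear(ac)
  oracle <- mc_gaussian_pairs(ac, function(x) pmin(1, pmax(-1, x)), n = 2e5)
  for (i in seq_along(out$values)) {
    expect_lt(abs(out$values[i] - oracle[[i]]$mean), 3 * oracle[[i]]$se + 1e-12)
  }
})

test_that("series zero lag equals the direct Gaussian expectation", {
  for (s2 in c(0.25, 1, 4)) {
    ac <- exp_autocorr(sigma2 = s2, n_half = 8)
    out <- map_autocorr_piecewise_linear(ac)
    direct <- integrate(function(z) pmin(1, pmax(-1, sqrt(s2) * z))^2 * dnorm(z),
                        -Inf, Inf, rel.tol = 1e-10)$value
    expect_equal(out$values[1], direct, tolerance = 1e-8)
  }
})

test_that("polynomial map reproduces the closed cubic form", {
  # for the cubic, C_phi = (1 + C0^2 - 2 C0) C + (2/3) C^3
  cu <- nonlinearity("cubic")
  for (s2 in c(0.25, 1, 2)) {
    ac <- exp_autocorr(sigma2 = s2, n_half = 16)
    out <- map_autocorr_polynomial(ac, cu$coefficients)
    expected <- (1 + s2^2 - 2 * s2) * ac$values + (2 / 3) * ac$values^3
    expect_equal(out$values, expected, tolerance = 1e-12)
  }
  # unit variance: the linear term vanishes identically
  ac1 <- exp_autocorr(sigma2 = 1, n_half = 8)
  out1 <- map_autocorr_polynomial(ac1, cu$coefficients)
  expect_equal(out1$values, (2 / 3) * ac1$values^3, tolerance = 1e-12)
  expect_equal(map_autocorr_polynomial(new_autocorr(rep(0, 9), 0.1),
                                       cu$coefficients)$values, rep(0, 9))
  expect_error(map_autocorr_polynomial(ac1, c(0.3, 0, 1)), "mean")
})

test_that("polynomial map matches the Monte-Carlo oracle", {
  cu <- nonlinearity("cubic")
  ac <- exp_autocorr(sigma2 = 0.25, n_half = 16, dt = 0.25)
  out <- map_autocorr_polynomial(ac, cu$coefficients)
  oracle <- mc_gaussian_pairs(ac, function(x) x - x^3 / 3, n = 2e5)
  for (i in seq_along(out$values)) {
    expect_lt(abs(out$values[i] - oracle[[i]]$mean), 3 * oracle[[i]]$se + 1e-12)
  }
})

test_that("quadrature map: identity, perfect correlation, cross-validation", {
  ac <- exp_autocorr(sigma2 = 0.8, n_half = 8, dt = 0.5)
  idm <- map_autocorr_quadrature(ac, nonlinearity("custom", fn = function(x) x))
  expect_equal(idm$values, ac$values, tolerance = 1e-8)
  # perfect correlation: C(tau) = C(0) collapses to E[phi^2]
  flat <- new_autocorr(rep(1, 5), 1)
  pl <- nonlinearity("piecewise_linear")
  outf <- map_autocorr_quadrature(flat, pl)
  expect_equal(outf$values[2], outf$values[1], tolerance = 1e-7)
  # series vs quadrature on a shared case
  out_q <- map_autocorr_quadrature(ac, pl)
  out_s <- map_autocorr_piecewise_linear(ac)
  expect_lt(max(abs(out_q$values - out_s$values)), 1e-6)
  # quadrature vs polynomial for the cubic
  cu <- nonlinearity("cubic")
  expect_lt(max(abs(map_autocorr_quadrature(ac, cu)$values -
                    map_autocorr_polynomial(ac, cu$coefficients)$values)), 1e-6)
})

test_that("Monte-Carlo spectrum map is unbiased for linear output", {
  sp <- new_spectrum(exp(-(seq(0, by = 0.01, length.out = 65) / 0.2)^2), 0.01)
  out <- map_spectrum_montecarlo(sp, nonlinearity("custom", fn = function(x) x),
                                 n_samples = 500, seed = 12)
  expect_lt(sum(abs(out$values - sp$values)) / sum(sp$values), 0.05)
  # determinism
  out2 <- map_spectrum_montecarlo(sp, nonlinearity("custom", fn = function(x) x),
                                  n_samples = 500, seed = 12)
  expect_identical(out$values, out2$values)
})

test_that("Monte-Carlo output variance matches quadrature for the clipped unit", {
  sp <- new_spectrum(rep(0.5, 65), 0.01)      # white, variance = 0.64
  v_in <- spectrum_variance(sp)
  pl <- nonlinearity("piecewise_linear")
  nrep <- 400
  out <- map_spectrum_montecarlo(sp, pl, n_samples = nrep, seed = 4)
  v_out <- spectrum_variance(out)
  expected <- ratechaos:::pl_second_moment(sqrt(v_in))
  # variance of a chi^2-ish average: generous 3-sigma band
  expect_lt(abs(v_out - expected), 3 * expected * sqrt(2 / (nrep * 64)))
})

test_that("pure oscillation through an odd nonlinearity yields odd harmonics only", {
  zero <- new_spectrum(rep(0, 129), 0.01)     # M = 256
  out <- map_spectrum_montecarlo(zero, nonlinearity("piecewise_linear"),
                                 oscillatory = c(2, 0.1), n_samples = 20, seed = 9)
  f <- spectrum_frequencies(out)
  bins <- round(f / 0.01)
  mass <- out$values
  odd_bins <- bins %% 10 == 0 & (bins / 10) %% 2 == 1
  expect_gt(sum(mass[odd_bins]), 0.99 * sum(mass))
  expect_error(map_spectrum_montecarlo(zero, nonlinearity("piecewise_linear"),
                                       oscillatory = c(1, 0.0153)), "grid")
})

test_that("bounded nonlinearity caps the output variance at one", {
  for (s2 in c(0.5, 2, 10)) {
    ac <- exp_autocorr(sigma2 = s2, n_half = 16)
    out <- map_autocorr_piecewise_linear(ac)
    expect_lt(out$values[1], 1)
    expect_true(all(abs(out$values) <= out$values[1] + 1e-12))
  }
})
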