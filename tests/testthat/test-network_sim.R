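test_that("connectivity sampling is reproducible with the stated statistics", {
  J <- sample_connectivity(500, 1.5, seed = 17)
  expect_identical(J, sample_connectivity(500, 1.5, seed = 17))
  expect_lt(abs(mean(J)), 4 * 1.5 / sqrt(500) / 500)   # 4 SE of the mean
  expect_lt(abs(stats::var(as.numeric(J)) - 1.5^2 / 500) / (1.5^2 / 500), 0.1)
  expect_equal(sample_connectivity(10, 0), matrix(0, 10, 10),
               ignore_attr = TRUE)
})

test_that("connectivity eigenvalues fill the disk of radius g", {
  J <- sample_connectivity(1000, 1.5, seed = 23)
  ev <- eigen(J, only.values = TRUE)$values
  expect_gte(mean(Mod(ev) <= 1.05 * 1.5), 0.99)
})

test_that("phase-randomized drive averages out across the population", {
  d <- phase_randomized_drive(0.5, 0.1, 1000, seed = 3)
  expect_identical(d$phases, phase_randomized_drive(0.5, 0.1, 1000, seed = 3)$phases)
  expect_true(all(d$phases >= 0 & d$phases < 2 * pi))
  # mean resultant of N random phasors is O(1/sqrt(N))
  resultant <- Mod(mean(exp(1i * d$phases)))
  expect_lt(resultant, 5 / sqrt(1000))
  z <- phase_randomized_drive(0, 0.1, 10)
  expect_equal(z$amplitude, 0)
})

test_that("uncoupled linear units relax exponentially at unit rate", {
  m <- adaptation_model(1, 0)    # beta = 0: x decays with unit rate
  J <- sample_connectivity(5, 0, seed = 1)
  res <- integrate_network(m, J, duration = 5, burn_in = 0,
                           record_step = 0.25, time_step = 0.05, seed = 2)
  x <- res$trajectories[, 1, ]
  expect_equal(x[, ncol(x)], x[, 1] * exp(-res$times[length(res$times)]),
               tolerance = 1e-4)
})

test_that("networks decay below threshold and sustain activity above it", {
  m <- adaptation_model(0.2, 0.5)
  gc_ <- critical_coupling(m)
  J <- sample_connectivity(300, 0.96 * gc_, seed = 8)
  below <- integrate_network(m, J, duration = 300, burn_in = 0, seed = 9)
  xb <- below$trajectories[, 1, ]
  expect_lt(max(abs(xb[, ncol(xb)])), 1e-3)
  J2 <- sample_connectivity(300, 1.3 * gc_, seed = 8)
  above <- integrate_network(m, J2, duration = 300, burn_in = 0, seed = 9)
  xa <- above$trajectories[, 1, ]
  expect_gt(mean(abs(xa[, ncol(xa)])), 0.05)
})

test_that("integration is deterministic and guards its step size", {
  m <- resonant_model()
  J <- sample_connectivity(20, 1.5, seed = 4)
  r1 <- integrate_network(m, J, duration = 20, burn_in = 5, seed = 6)
  r2 <- integrate_network(m, J, duration = 20, burn_in = 5, seed = 6)
  expect_identical(r1$trajectories, r2$trajectories)
  expect_error(integrate_network(adaptation_model(5, 1), J, duration = 10,
                                 time_step = 0.05),
               "time_step")
})

test_that("spectral estimator recovers known spectra", {
  # pure sinusoid: mass concentrated at the drive bin
  tt <- seq(0, by = 0.25, length.out = 4096)
  x <- array(0, dim = c(3, 1, length(tt)))
  for (i in 1:3) x[i, 1, ] <- sin(2 * pi * 0.125 * tt + i)
  fake <- structure(list(trajectories = x, time_step = 0.25, times = tt,
                         burn_in = 0, seeds = list(), parameters = list()),
                    class = "SimulationResult")
  sp <- estimate_spectrum(fake, segment_length = 1024)
  f <- spectrum_frequencies(sp)
  bin <- which.min(abs(f - 0.125))
  frac <- sum(sp$values[(bin - 1):(bin + 1)]) / sum(sp$values)
  expect_gte(frac, 0.95)
  # white noise: flat spectrum, correct total variance
  set.seed(10)
  xw <- array(rnorm(20 * 4096), dim = c(20, 1, 4096))
  fakew <- structure(list(trajectories = xw, time_step = 0.5, times = NULL,
                          burn_in = 0, seeds = list(), parameters = list()),
                     class = "SimulationResult")
  spw <- estimate_spectrum(fakew, segment_length = 256)
  # normalization is to the per-unit demeaned variance
  expect_equal(spectrum_variance(spw), mean(xw^2), tolerance = 1e-3)
  expect_lt(stats::sd(spw$values[-c(1, length(spw$values))]) /
            mean(spw$values), 0.15)
})

test_that("step-size halving changes the spectrum no more than resampling does", {
  # chaotic trajectories decorrelate, so two step sizes cannot be compared
  # pathwise; the integrator check is that halving the step moves the
  # spectral estimate by no more than an independent realization does
  m <- resonant_model()
  gc_ <- critical_coupling(m)
  J <- sample_connectivity(100, 2 * gc_, seed = 12)
  r1 <- integrate_network(m, J, duration = 400, burn_in = 100,
                          time_step = 0.05, seed = 13)
  r2 <- integrate_network(m, J, duration = 400, burn_in = 100,
                          time_step = 0.025, seed = 13)
  r3 <- integrate_network(m, J, duration = 400, burn_in = 100,
                          time_step = 0.05, seed = 14)
  s1 <- estimate_spectrum(r1, segment_length = 512)
  s2 <- estimate_spectrum(r2, segment_length = 512)
  s3 <- estimate_spectrum(r3, segment_length = 512)
  d_step <- spectrum_distance(s1, s2, f_max = 0.5)
  d_seed <- spectrum_distance(s1, s3, f_max = 0.5)
  expect_lt(d_step, 2 * d_seed)
})

test_that("activation distribution is Gaussian for a linear network", {
  # linear units driven by white noise: exactly Gaussian
  set.seed(14)
  xg <- array(rnorm(40 * 2000, sd = 0.7), dim = c(40, 1, 2000))
  fake <- structure(list(trajectories = xg, time_step = 0.5, times = NULL,
                         burn_in = 0, seeds = list(), parameters = list()),
                    class = "SimulationResult")
  ad <- activation_distribution(fake, variance = 0.49)
  expect_lt(ad$ks_distance, 0.01)
  expect_equal(ad$empirical_variance, 0.49, tolerance = 0.02)
})

test_that("heterogeneous adaptation reproduces the homogeneous spectrum shape", {
  # a single finite network gives a noisy periodogram, so the comparison
  # uses stable statistics: the power-weighted peak centroid and
  # band-integrated powers
  m <- resonant_model()
  gc_ <- critical_coupling(m)
  N <- 400
  J <- sample_connectivity(N, 2 * gc_, seed = 15)
  beta_i <- with(list(), {set.seed(16); rnorm(N, 1, 0.5)})
  hom <- integrate_network(m, J, duration = 800, burn_in = 100, seed = 17)
  het <- suppressWarnings(
    integrate_network(m, J, duration = 800, burn_in = 100, seed = 17,
                      heterogeneity = beta_i))
  s_hom <- estimate_spectrum(hom, segment_length = 2048)
  s_het <- estimate_spectrum(het, segment_length = 2048)
  f <- spectrum_frequencies(s_hom)
  centroid <- function(s) {
    w <- f >= 0.05 & f <= 0.2
    sum(f[w] * s$values[w]) / sum(s$values[w])
  }
  expect_lt(abs(centroid(s_hom) - centroid(s_het)), 0.01)
  band <- function(s, lo, hi) sum(s$values[f >= lo & f < hi])
  expect_lt(abs(band(s_het, 0.05, 0.2) / band(s_hom, 0.05, 0.2) - 1), 0.3)
  # negative heterogeneous beta_i trigger a warning
  expect_warning(
    integrate_network(m, sample_connectivity(20, 1, seed = 1),
                      duration = 10, burn_in = 0, seed = 2,
                      heterogeneity = c(rep(1, 19), -0.2)),
    "negative")
})
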