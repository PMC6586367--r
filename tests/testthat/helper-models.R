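# shared fixtures, built in code

resonant_model <- function() adaptation_model(0.25, 1)
nonresonant_model <- function() adaptation_model(1, 0.1)

# the two published multi-dimensional interaction matrices (3-D and 4-D)
table_matrix_3d <- function() {
  matrix(c(-1, -1, -1,
           0.1, 0.1, 1.7,
           0.1, -0.4, -0.5), 3, 3, byrow = TRUE)
}
table_matrix_4d <- function() {
  matrix(c(-1, -1, -1, -1,
           1, -0.5, -0.65, -0.6,
           1, 0.35, -0.05, -0.57,
           1, 0.35, 0.28, -0.005), 4, 4, byrow = TRUE)
}

# coarse solver settings for fast tests
fast_config <- function(...) solver_config(freq_step = 0.002, max_freq = 1, ...)

# an exponential-decay autocorrelation on a small power-of-two grid
exp_autocorr <- function(sigma2 = 1, tau0 = 1, n_half = 64, dt = 0.1) {
  lags <- seq(0, by = dt, length.out = n_half + 1)
  new_autocorr(sigma2 * exp(-lags / tau0), dt)
}

# Monte-Carlo oracle: push Gaussian pairs with correlation C(tau) through phi
# and average; returns mean and standard error per lag
mc_gaussian_pairs <- function(autocorr, phi, n = 1e5, seed = 99) {
  C <- autocorr$values
  s2 <- C[1]
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    z1 <- stats::rnorm(n, sd = sqrt(s2))
    lapply(seq_along(C), function(i) {
      rho <- C[i] / s2
      z2 <- rho * z1 + sqrt(max(s2 * (1 - rho^2), 0)) * stats::rnorm(n)
      v <- phi(z1) * phi(z2)
      list(mean = mean(v), se = stats::sd(v) / sqrt(n))
    })
  })
}
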