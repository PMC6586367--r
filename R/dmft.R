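#' Solver configuration for the self-consistent mean-field equations
#'
#' @param freq_step frequency bin `df` (default 0.001).
#' @param max_freq requested maximum frequency of the grid (default 2; the
#'   grid is rounded up to a power-of-two circle, see [spectrum_grid()]).
#' @param tolerance convergence tolerance on the relative L1 change of
#'   `S_x` between iterations (default `1e-6`; stochastic nonlinear steps
#'   are judged on a 5-iteration moving average instead, for which a looser
#'   default applies in [solve_dmft_driven()]).
#' @param max_iterations iteration cap.
#' @param damping initial damping factor `alpha` in `(0, 1]`; the update is
#'   `S <- (1 - alpha) S + alpha S_new`. When the residual sequence
#'   oscillates, `alpha` is halved automatically (floor 0.25).
#' @param nonlinearity_method one of `"series_pl"` (Hermite series for the
#'   piecewise-linear unit; the default and fastest), `"polynomial"`,
#'   `"quadrature"`, `"montecarlo"`.
#' @param n_samples Monte-Carlo sample paths per iteration (montecarlo
#'   method only).
#' @param seed root seed for stochastic nonlinear steps; per-iteration
#'   sub-seeds are derived from it.
#' @param init_variance variance of the constant (white) initial rate
#'   spectrum. The level is arbitrary — the fixed point must not depend on
#'   it, which is tested — and defaults to 1.
#' @return a `SolverConfig` list.
#' @export
solver_config <- function(freq_step = 0.001, max_freq = 2,
                          tolerance = 1e-6, max_iterations = 1000L,
                          damping = 1,
                          nonlinearity_method = c("series_pl", "polynomial",
                                                  "quadrature", "montecarlo"),
                          n_samples = 256L, seed = 1L, init_variance = 1) {
  stopifnot(tolerance > 0, max_iterations >= 1, damping > 0, damping <= 1)
  structure(list(freq_step = freq_step, max_freq = max_freq,
                 tolerance = tolerance, max_iterations = as.integer(max_iterations),
                 damping = damping,
                 nonlinearity_method = match.arg(nonlinearity_method),
                 n_samples = as.integer(n_samples), seed = seed,
                 init_variance = init_variance),
            class = "SolverConfig")
}

# One nonlinear step S_x -> S_phi via the configured method.
nonlinear_step <- function(spec_x, model, config, iter = 0L) {
  switch(config$nonlinearity_method,
    series_pl = {
      if (model$nonlinearity$kind != "piecewise_linear")
        stopf("series_pl method requires the piecewise_linear nonlinearity")
      autocorr_to_spectrum(
        map_autocorr_piecewise_linear(spectrum_to_autocorr(spec_x)))
    },
    polynomial = {
      coefs <- model$nonlinearity$coefficients
      if (is.null(coefs))
        stopf("polynomial method requires a polynomial nonlinearity")
      autocorr_to_spectrum(
        map_autocorr_polynomial(spectrum_to_autocorr(spec_x), coefs))
    },
    quadrature = autocorr_to_spectrum(
      map_autocorr_quadrature(spectrum_to_autocorr(spec_x), model$nonlinearity)),
    montecarlo = map_spectrum_montecarlo(
      spec_x, model$nonlinearity, n_samples = config$n_samples,
      seed = sub_seed(config$seed, "mc-step", iter))
  )
}

#' Solve the self-consistent mean-field power spectrum
#'
#' Iterates the fixed-point map
#' \deqn{S_x^{(n+1)}(f) = \tilde G(f)\left(g^2 S_{\phi(x)}^{(n)}(f)
#'       + S_I(f)\right),}
#' where the nonlinear step \eqn{S_x \mapsto S_{\phi(x)}} is computed by the
#' configured method (autocorrelation-domain methods are bridged by the
#' discrete Wiener–Khinchin transform). The iteration starts from a constant
#' (white) rate spectrum with unit variance. Below the critical coupling the
#' iteration contracts to the all-zero spectrum (detected when
#' `max S_x < 1e-10`); above it, it converges to the nonzero continuous
#' spectrum of the chaotic phase.
#'
#' @param model a `RateModel`.
#' @param g non-negative coupling strength.
#' @param input_spectrum optional `Spectrum` of external noise `S_I` on the
#'   same grid.
#' @param config a [solver_config()].
#' @return a `DMFTSolution` with fields `spectrum_x`, `spectrum_rate`,
#'   `variance`, `iterations`, `converged`, `zero_solution`,
#'   `residual_history`, `oscillatory_peaks` (empty here), and the gain
#'   values on the grid.
#' @examples
#' \donttest{
#' m <- adaptation_model(0.25, 1)
#' gc <- critical_coupling(m)
#' sol <- solve_dmft(m, 2 * gc)
#' sol$variance
#' }
#' @export
solve_dmft <- function(model, g, input_spectrum = NULL,
                       config = solver_config()) {
  stopifnot(inherits(model, "RateModel"), is_scalar_num(g), g >= 0)
  grid <- spectrum_grid(config$freq_step, config$max_freq)
  freqs <- seq(0, by = grid$freq_step, length.out = grid$n_half + 1)
  G <- if (!is.null(model$gain_override)) model$gain_override
       else gain_values(model, freqs)
  if (length(G) != length(freqs)) stopf("gain vector length mismatch")
  SI <- input_values_on_grid(input_spectrum, grid)
  # initial white rate spectrum (configurable level, variance 1 by default)
  v0 <- config$init_variance %||% 1
  S_phi <- new_spectrum(rep(v0 / (grid$M * grid$freq_step), grid$n_half + 1),
                        grid$freq_step)
  S_x <- NULL
  residuals <- numeric(0)
  alpha <- config$damping
  converged <- FALSE
  zero_solution <- FALSE
  iter <- 0L
  while (iter < config$max_iterations) {
    iter <- iter + 1L
    S_new <- G * (g^2 * S_phi$values + SI)
    if (any(!is.finite(S_new)))
      stopf("solver diverged at iteration %d (non-finite spectrum)", iter)
    if (is.null(S_x)) {
      S_x <- new_spectrum(S_new, grid$freq_step)
    } else {
      upd <- (1 - alpha) * S_x$values + alpha * S_new
      res <- sum(abs(upd - S_x$values)) / max(sum(S_x$values), 1e-300)
      residuals <- c(residuals, res)
      S_x <- new_spectrum(upd, grid$freq_step)
      n <- length(residuals)
      if (res <= config$tolerance) { converged <- TRUE; break }
      if (n >= 4 && alpha > 0.25 &&
          residuals[n] > residuals[n - 1] &&
          residuals[n - 1] < residuals[n - 2] &&
          residuals[n - 2] > residuals[n - 3])
        alpha <- max(alpha / 2, 0.25)
    }
    if (max(S_x$values) < 1e-10) {
      converged <- TRUE; zero_solution <- TRUE; break
    }
    if (spectrum_variance(S_x) > 1e8)
      stopf("solver diverged at iteration %d (variance blow-up)", iter)
    S_phi <- nonlinear_step(S_x, model, config, iter)
  }
  if (zero_solution) {
    S_x <- new_spectrum(rep(0, grid$n_half + 1), grid$freq_step)
    S_phi <- S_x
  } else {
    S_phi <- nonlinear_step(S_x, model, config, iter + 1L)
  }
  new_dmft_solution(model = model, g = g, spectrum_x = S_x,
                    spectrum_rate = S_phi, gain = G, grid = grid,
                    input = SI,
                    oscillatory_peaks = numeric(0), drive = NULL,
                    iterations = iter, converged = converged,
                    zero_solution = zero_solution,
                    residual_history = residuals, config = config)
}

input_values_on_grid <- function(input_spectrum, grid) {
  if (is.null(input_spectrum)) return(rep(0, grid$n_half + 1))
  stopifnot(inherits(input_spectrum, "Spectrum"))
  if (abs(input_spectrum$freq_step - grid$freq_step) > 1e-12 ||
      length(input_spectrum$values) != grid$n_half + 1)
    stopf("input spectrum grid mismatch (df = %g, expected %g)",
          input_spectrum$freq_step, grid$freq_step)
  input_spectrum$values
}

new_dmft_solution <- function(...) {
  structure(list(...), class = "DMFTSolution")
}

#' @export
print.DMFTSolution <- function(x, ...) {
  cat("<DMFTSolution> g =", x$g,
      "|", if (x$zero_solution) "zero (quiescent) solution"
           else "nonzero (chaotic) solution",
      "\n  iterations:", x$iterations,
      "| converged:", x$converged,
      "| variance:", format(solution_variance(x)), "\n")
  if (length(x$oscillatory_peaks))
    cat("  oscillatory peaks b_k:",
        paste(format(x$oscillatory_peaks, digits = 4), collapse = ", "), "\n")
  invisible(x)
}

#' Total variance of a mean-field solution
#'
#' `df * sum` of the (two-sided) background spectrum plus `2 * sum(b_k)`
#' when oscillatory peaks are present.
#'
#' @param solution a `DMFTSolution`.
#' @return non-negative scalar.
#' @export
solution_variance <- function(solution) {
  stopifnot(inherits(solution, "DMFTSolution"))
  spectrum_variance(solution$spectrum_x) + 2 * sum(solution$oscillatory_peaks)
}

#' Effective single-unit gain under heterogeneous adaptation strength
#'
#' When the adaptation strength is quenched-random across units,
#' \eqn{\beta_i \sim N(\bar\beta, \sigma_\beta^2)}, the network's
#' self-consistency involves the effective filter
#' \deqn{\tilde G_H(f) = \frac{\tilde G(f)}
#'   {1 - \frac{\gamma^2\sigma_\beta^2}{\gamma^2+\omega^2}\tilde G(f)},
#'   \qquad \omega = 2\pi f,}
#' which exceeds \eqn{\tilde G} at low frequencies and reduces to it for
#' \eqn{\sigma_\beta = 0}.
#'
#' @param gamma,beta_mean homogeneous adaptation parameters (the mean).
#' @param beta_sd standard deviation \eqn{\sigma_\beta} of the adaptation
#'   strength.
#' @param frequencies numeric vector of frequencies.
#' @return the effective squared gain values; errors if the denominator is
#'   not strictly positive at every requested frequency (heterogeneity too
#'   strong for the effective-filter description).
#' @export
heterogeneous_gain <- function(gamma, beta_mean, beta_sd, frequencies) {
  stopifnot(is_scalar_num(gamma), gamma > 0, is_scalar_num(beta_mean),
            is_scalar_num(beta_sd), beta_sd >= 0)
  G <- gain_adaptation(gamma, beta_mean, frequencies)
  w2 <- (2 * pi * frequencies)^2
  den <- 1 - (gamma^2 * beta_sd^2 / (gamma^2 + w2)) * G
  if (any(den <= 0))
    stopf("effective heterogeneous filter invalid: denominator <= 0 at f = %g",
          frequencies[which(den <= 0)[1]])
  G / den
}

#' Mean-field solution with a heterogeneous-adaptation effective filter
#'
#' Runs [solve_dmft()] with \eqn{\tilde G} replaced by the effective filter
#' of [heterogeneous_gain()].
#'
#' @inheritParams heterogeneous_gain
#' @param g coupling strength.
#' @param config a [solver_config()].
#' @return a `DMFTSolution`.
#' @export
solve_dmft_heterogeneous <- function(gamma, beta_mean, beta_sd, g,
                                     config = solver_config()) {
  model <- adaptation_model(gamma, beta_mean)
  grid <- spectrum_grid(config$freq_step, config$max_freq)
  freqs <- seq(0, by = grid$freq_step, length.out = grid$n_half + 1)
  GH <- heterogeneous_gain(gamma, beta_mean, beta_sd, freqs)
  solve_dmft_with_gain(model, g, GH, config)
}

# solve_dmft with an externally supplied gain vector on the solver grid
solve_dmft_with_gain <- function(model, g, gain_values_vec, config) {
  model$gain_override <- gain_values_vec
  solve_dmft(model, g, NULL, config)
}

#' Linear-response prediction below criticality
#'
#' For `g < g_c` and weak drive, the network response is characterized by
#' the mean-field susceptibility
#' \deqn{|\tilde\chi_\beta(f)|^2 = \frac{\tilde G(f)}{1 - g^2\tilde G(f)},}
#' the output spectrum is
#' \eqn{S_x = |\tilde\chi_\beta|^2 (S_I + S_\eta)} and the signal-to-noise
#' ratio at the drive frequency,
#' \eqn{\mathrm{SNR}(f_I) = A_I^2/(4 S_\eta(f_I)\Delta f)}, is independent
#' of the single-unit parameters: signal and external noise are shaped by
#' the same filter.
#'
#' @param model a `RateModel`.
#' @param g coupling, strictly below the critical value.
#' @param noise_spectrum external noise `Spectrum` \eqn{S_\eta}.
#' @param amplitude,f_I oscillatory drive amplitude `A_I` and frequency
#'   (must sit on the noise spectrum's grid).
#' @return list with `spectrum` (output `Spectrum`, background part),
#'   `snr`, and the susceptibility-squared values `chi2`.
#' @export
linear_response_prediction <- function(model, g, noise_spectrum, amplitude, f_I) {
  stopifnot(inherits(model, "RateModel"), inherits(noise_spectrum, "Spectrum"),
            is_scalar_num(g), g >= 0, is_scalar_num(amplitude), amplitude >= 0)
  df <- noise_spectrum$freq_step
  freqs <- spectrum_frequencies(noise_spectrum)
  G <- gain_values(model, freqs)
  # the pole sits at the true maximum of the gain, not the grid maximum
  if (g^2 * max_gain(model)$value >= 1)
    stopf("linear response theory inapplicable: g^2 max G >= 1 (g >= g_c)")
  chi2 <- G / (1 - g^2 * G)
  bin <- f_I / df
  if (abs(bin - round(bin)) > 1e-8) stopf("f_I = %g is not on the grid", f_I)
  bin <- as.integer(round(bin)) + 1L
  S_out <- chi2 * noise_spectrum$values
  # signal path: delta line of integrated one-sided mass A_I^2/4 at f_I
  A_osc <- chi2[bin] * amplitude^2 / (4 * df)
  A_bkg <- chi2[bin] * noise_spectrum$values[bin]
  list(spectrum = new_spectrum(S_out, df), chi2 = chi2,
       snr = A_osc / A_bkg,
       A_osc = A_osc, A_bkg = A_bkg)
}

#' Sharpening of the gain over the first solver iterations
#'
#' Starting from a white spectrum, iterate `n` times and return each
#' normalized iterate \eqn{\hat S_x^{(k)} = S_x^{(k)}/\max S_x^{(k)}}
#' together with the first-order prediction \eqn{(\hat G(f))^k}: the
#' recurrent network sharpens the single-unit response, narrowing the
#' preferred band with every iteration.
#'
#' @param model a `RateModel`.
#' @param g coupling.
#' @param n_iterations how many iterates to record (small, typically <= 5).
#' @param config a [solver_config()].
#' @return list with `frequencies`, `iterates` (matrix, one column per
#'   iteration), `predictions` (same shape), `gain_normalized`.
#' @export
sharpening_iterates <- function(model, g, n_iterations = 3,
                                config = solver_config()) {
  stopifnot(n_iterations >= 1)
  grid <- spectrum_grid(config$freq_step, config$max_freq)
  freqs <- seq(0, by = grid$freq_step, length.out = grid$n_half + 1)
  G <- gain_values(model, freqs)
  Ghat <- G / max(G)
  S_phi <- new_spectrum(rep(1 / (grid$M * grid$freq_step), grid$n_half + 1),
                        grid$freq_step)
  iterates <- matrix(NA_real_, length(freqs), n_iterations)
  predictions <- matrix(NA_real_, length(freqs), n_iterations)
  for (k in seq_len(n_iterations)) {
    S_x <- new_spectrum(G * g^2 * S_phi$values, grid$freq_step)
    iterates[, k] <- S_x$values / max(S_x$values)
    predictions[, k] <- Ghat^k
    if (k < n_iterations) S_phi <- nonlinear_step(S_x, model, config, k)
  }
  list(frequencies = freqs, iterates = iterates, predictions = predictions,
       gain_normalized = Ghat)
}

#' Mean-field solution under oscillatory drive
#'
#' Each unit receives \eqn{I(t) = A_I\cos(2\pi f_I t + \theta_i)} with
#' independent uniform phases, i.e. an input spectrum with a delta line of
#' one-sided mass \eqn{A_I^2/4} at \eqn{f_I}. The activation is split into
#' a Gaussian background with continuous spectrum \eqn{S_{bkg}} and an
#' oscillatory part carried as non-negative line masses \eqn{b_k} at the
#' harmonics \eqn{k f_I}. Because both the connectivity and the drive
#' phases are random across units, the periodic power returning through the
#' recurrent loop is incoherent with a unit's own drive phase; the lines
#' therefore close in power, not in amplitude:
#' \deqn{S_{bkg} \leftarrow \tilde G\, g^2 S^{\phi}_{bkg}, \qquad
#'   b_k = b^{dir}_k + b^{net}_k, \quad
#'   b^{net}_k \leftarrow \tilde G(k f_I)\, g^2 b_k^{\phi}, \quad
#'   b^{dir}_k = \delta_{k1}\tilde G(f_I) A_I^2/4.}
#' The two line contributions differ in kind, and the distinction matters
#' quantitatively: a unit's response to its own drive has deterministic
#' amplitude, whereas the line power arriving through the random network is
#' a complex-Gaussian phasor across units (Rayleigh-distributed amplitude).
#' The Monte-Carlo nonlinear step therefore adds, per sample path, the
#' direct line as a fixed-amplitude sinusoid and each network line as a
#' sinusoid whose complex amplitude is drawn from
#' \eqn{CN(0, b^{net}_k)}, all with independent uniform phases. (Injecting
#' the full mean power at fixed amplitude overstates the nonlinear
#' transmission — it is concave in power — and lets the resonant loop run
#' away into a spurious entrained state.)
#'
#' The transmitted line mass at each harmonic is estimated without bias by
#' injecting the same line phasors into two independent background sample
#' paths and averaging the cross-periodogram at the harmonic bin: the
#' background contributions are independent and cancel in expectation,
#' leaving exactly the coherent line power. (The alternative — reading the
#' line as the excess of the bin over its interpolated neighbors — is
#' biased wherever the background is curved, and when the drive sits on
#' the chaotic resonance the loop amplifies that curvature excess into a
#' spuriously strong line and a blurred signal-to-noise minimum.) The rate
#' background is the averaged periodogram with the line mass subtracted at
#' the harmonic bins. Residuals of this stochastic iteration are assessed
#' on a 5-iteration moving average, and the reported solution averages the
#' final iterates to suppress Monte-Carlo noise.
#'
#' @param model a `RateModel`.
#' @param g coupling strength.
#' @param amplitude drive amplitude `A_I >= 0`.
#' @param f_I drive frequency; must be a positive multiple of the grid bin.
#' @param config a [solver_config()]; for this stochastic solver the
#'   tolerance default is `2e-2` on the moving-average relative change and
#'   `max_iterations` defaults to 80.
#' @param n_harmonics cap on the number of harmonics tracked.
#' @param average_last how many final iterates to average for the reported
#'   solution.
#' @return a `DMFTSolution` whose `oscillatory_peaks` holds the one-sided
#'   line masses `b_k` (named by harmonic index).
#' @export
solve_dmft_driven <- function(model, g, amplitude, f_I,
                              config = solver_config(tolerance = 2e-2,
                                                     max_iterations = 80L),
                              n_harmonics = 10L, average_last = 20L) {
  stopifnot(inherits(model, "RateModel"), is_scalar_num(g), g >= 0,
            is_scalar_num(amplitude), amplitude >= 0)
  if (amplitude == 0) return(solve_dmft(model, g, NULL, config))
  grid <- spectrum_grid(config$freq_step, config$max_freq)
  df <- grid$freq_step
  m_I <- f_I / df
  if (abs(m_I - round(m_I)) > 1e-8 || round(m_I) < 1)
    stopf("f_I = %g must be a positive multiple of the frequency bin %g", f_I, df)
  m_I <- as.integer(round(m_I))
  K <- max(1L, min(n_harmonics, floor(grid$n_half / m_I) - 1L))
  freqs <- seq(0, by = df, length.out = grid$n_half + 1)
  G <- if (!is.null(model$gain_override)) model$gain_override
       else gain_values(model, freqs)
  G_harm <- G[(1:K) * m_I + 1L]
  phi <- model$nonlinearity$fn
  M <- grid$M
  # initialization: undriven chaotic background, single-pass drive line
  base_cfg <- config
  base_cfg$nonlinearity_method <- "series_pl"
  base_cfg$tolerance <- 1e-6
  base_cfg$max_iterations <- 1000L
  init <- try(solve_dmft(model, g, NULL, base_cfg), silent = TRUE)
  S_bkg <- if (!inherits(init, "try-error")) init$spectrum_x$values
           else G * 0
  b_dir <- c(G_harm[1] * amplitude^2 / 4, rep(0, K - 1))  # own-drive line
  b_net <- numeric(K)                                     # network lines
  harm_bins <- (1:K) * m_I + 1L          # R indices of harmonic bins
  tvec_phase <- 2 * pi * m_I * (0:(M - 1)) / M   # fundamental phase ramp
  residuals <- numeric(0)
  converged <- FALSE
  S_hist <- list(); b_hist <- list()
  alpha <- config$damping
  for (iter in seq_len(config$max_iterations)) {
    seed_it <- sub_seed(config$seed, "driven-mc", iter)
    spec_obj <- new_spectrum(S_bkg, df)
    acc_S <- numeric(M)
    acc_b <- numeric(K)
    with_seed(seed_it, {
      for (s in seq_len(config$n_samples)) {
        line <- numeric(M)
        for (k in seq_len(K)) {
          # line phasor: deterministic own-drive part plus complex-Gaussian
          # network part (Rayleigh amplitude across mean-field samples)
          c_k <- 0i
          if (b_dir[k] > 0)
            c_k <- sqrt(b_dir[k]) * exp(1i * stats::runif(1, 0, 2 * pi))
          if (b_net[k] > 0)
            c_k <- c_k + complex(real = stats::rnorm(1, sd = sqrt(b_net[k] / 2)),
                                 imaginary = stats::rnorm(1, sd = sqrt(b_net[k] / 2)))
          a <- 2 * Mod(c_k)
          if (a > 0) {
            th <- Arg(c_k)
            line <- line + a * cos(k * tvec_phase + th)
          }
        }
        # same line through two independent backgrounds: the harmonic-bin
        # cross-periodogram is an unbiased estimate of the line mass
        yf1 <- stats::fft(phi(gaussian_path(spec_obj) + line)) / M
        yf2 <- stats::fft(phi(gaussian_path(spec_obj) + line)) / M
        acc_S <- acc_S + (Mod(yf1)^2 + Mod(yf2)^2) / (2 * df)
        acc_b <- acc_b + Re(yf1[harm_bins] * Conj(yf2[harm_bins]))
      }
    })
    S_phi_full <- acc_S / config$n_samples
    b_phi <- pmax(acc_b / config$n_samples, 0)
    S_phi <- S_phi_full[seq_len(M / 2 + 1)]
    S_phi[2:(M / 2)] <- 0.5 * (S_phi[2:(M / 2)] + rev(S_phi_full[(M / 2 + 2):M]))
    # the rate background at the harmonic bins is what remains after the
    # line mass is removed
    for (k in seq_len(K)) {
      b <- harm_bins[k]
      S_phi[b] <- max(S_phi[b] - b_phi[k] / df, 0)
    }
    S_new <- G * g^2 * S_phi
    # network lines: everything the rate lines send back through the
    # coupling; the direct line is fixed at b_dir and not iterated
    b_net_new <- G_harm * g^2 * b_phi
    S_upd <- (1 - alpha) * S_bkg + alpha * S_new
    b_upd <- (1 - alpha) * b_net + alpha * b_net_new
    b_tot_old <- b_dir + b_net
    b_tot <- b_dir + b_upd
    res <- (sum(abs(S_upd - S_bkg)) * df + 2 * sum(abs(b_tot - b_tot_old))) /
      max(sum(S_bkg) * df + 2 * sum(b_tot_old), 1e-300)
    residuals <- c(residuals, res)
    S_bkg <- S_upd
    b_net <- b_upd
    S_hist[[length(S_hist) + 1L]] <- S_bkg
    b_hist[[length(b_hist) + 1L]] <- b_dir + b_net
    if (length(S_hist) > average_last) {
      S_hist <- S_hist[-1]; b_hist <- b_hist[-1]
    }
    n <- length(residuals)
    if (n >= 5 && mean(residuals[(n - 4):n]) <= config$tolerance) {
      converged <- TRUE
      break
    }
  }
  # average retained iterates to suppress Monte-Carlo noise
  S_avg <- Reduce(`+`, S_hist) / length(S_hist)
  b_avg <- Reduce(`+`, b_hist) / length(b_hist)
  names(b_avg) <- as.character(seq_len(K))
  S_x <- new_spectrum(S_avg, df)
  new_dmft_solution(model = model, g = g, spectrum_x = S_x,
                    spectrum_rate = NULL, gain = G, grid = grid,
                    input = NULL,
                    oscillatory_peaks = b_avg,
                    drive = list(amplitude = amplitude, f_I = f_I),
                    iterations = length(residuals), converged = converged,
                    zero_solution = max(S_avg) < 1e-10,
                    residual_history = residuals, config = config)
}
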