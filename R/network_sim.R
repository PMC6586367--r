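#' Sample a Gaussian random connectivity matrix
#'
#' Entries are i.i.d. \eqn{N(0, g^2/N)}; in the large-`N` limit the
#' eigenvalues fill the disk of radius `g` (circular law).
#'
#' @param N network size (`>= 2`).
#' @param g coupling strength (`>= 0`).
#' @param seed integer seed; the same seed reproduces the same matrix.
#' @return an `N x N` matrix with attributes `g` and `seed`.
#' @export
sample_connectivity <- function(N, g, seed = 1L) {
  stopifnot(N >= 2, is_scalar_num(g), g >= 0)
  J <- with_seed(seed, matrix(stats::rnorm(N * N, sd = if (g > 0) g / sqrt(N) else 0),
                              N, N))
  if (g == 0) J[] <- 0
  attr(J, "g") <- g
  attr(J, "seed") <- seed
  J
}

#' Phase-randomized sinusoidal drive
#'
#' Each unit receives \eqn{I_i(t) = A_I \cos(2\pi f_I t + \theta_i)} with
#' independent uniform phases, so the population-average input vanishes as
#' `N` grows and the driven network still reaches a stationary state.
#'
#' @param amplitude drive amplitude `A_I >= 0`.
#' @param f_I drive frequency (`> 0`).
#' @param N number of units.
#' @param seed integer seed for the phases.
#' @return a `DriveSpec` list with `amplitude`, `f_I`, `phases`.
#' @export
phase_randomized_drive <- function(amplitude, f_I, N, seed = 1L) {
  stopifnot(is_scalar_num(amplitude), amplitude >= 0,
            is_scalar_num(f_I), f_I > 0, N >= 1)
  phases <- with_seed(seed, stats::runif(N, 0, 2 * pi))
  structure(list(amplitude = amplitude, f_I = f_I, phases = phases),
            class = "DriveSpec")
}

#' Integrate the full microscopic network
#'
#' Fixed-step fourth-order Runge–Kutta integration of the `N x D` coupled
#' rate equations
#' \deqn{\dot x_i^\alpha = \sum_\beta A^{\alpha\beta} x_i^\beta +
#'   \delta^{\alpha 1}\Big(\sum_j J_{ij}\,\phi(x_j^1) + I_i(t)\Big).}
#' Initial activations are drawn from a centered Gaussian (scale
#' `init_scale`), auxiliary variables start at zero. The first `burn_in`
#' time units are discarded; recorded states are thinned to `record_step`.
#'
#' @param model a `RateModel`.
#' @param connectivity `N x N` matrix from [sample_connectivity()].
#' @param drive optional [phase_randomized_drive()].
#' @param duration post-burn-in simulated time (default 2000).
#' @param time_step integration step (default 0.05; must resolve the
#'   fastest model timescale).
#' @param burn_in discarded initial time (default 200).
#' @param record_step recording interval (multiple of `time_step`).
#' @param record_variables indices of model variables to keep (default 1,
#'   the activation).
#' @param seed seed for the initial condition.
#' @param init_scale standard deviation of the initial activations.
#' @param heterogeneity optional vector of per-unit adaptation strengths
#'   `beta_i` (adaptation models only; overrides the model's `beta` row).
#' @return a `SimulationResult` with `trajectories` (array
#'   `unit x variable x time`), `time_step` = `record_step`, `times`,
#'   `burn_in`, `seeds`, `parameters`.
#' @export
integrate_network <- function(model, connectivity, drive = NULL,
                              duration = 2000, time_step = 0.05,
                              burn_in = 200, record_step = 0.25,
                              record_variables = 1L,
                              seed = 1L, init_scale = 0.5,
                              heterogeneity = NULL) {
  stopifnot(inherits(model, "RateModel"), is.matrix(connectivity),
            nrow(connectivity) == ncol(connectivity),
            duration > 0, time_step > 0, burn_in >= 0)
  N <- nrow(connectivity)
  D <- model$dim
  # the integration step must resolve the fastest timescale of A
  fastest <- 1 / max(abs(Re(model$eigenvalues)))
  if (time_step > 0.1 * fastest)
    stopf("time_step %g too coarse for fastest model timescale %g",
          time_step, fastest)
  thin <- round(record_step / time_step)
  if (abs(thin * time_step - record_step) > 1e-9 || thin < 1)
    stopf("record_step must be a positive multiple of time_step")
  A <- model$interaction
  phi <- model$nonlinearity$fn
  if (!is.null(heterogeneity)) {
    if (!is_adaptation_model(model))
      stopf("heterogeneity is only supported for adaptation models")
    stopifnot(length(heterogeneity) == N)
    if (any(heterogeneity < 0))
      warning(sprintf("%.1f%% of heterogeneous beta_i are negative",
                      100 * mean(heterogeneity < 0)))
  }
  drive_fn <- if (is.null(drive) || drive$amplitude == 0) NULL else {
    stopifnot(length(drive$phases) == N)
    function(t) drive$amplitude * cos(2 * pi * drive$f_I * t + drive$phases)
  }
  gamma <- model$gamma
  deriv <- function(X, t) {
    # X is D x N; returns dX/dt
    dX <- A %*% X
    if (!is.null(heterogeneity))
      dX[2, ] <- gamma * heterogeneity * X[1, ] - gamma * X[2, ]
    inp <- drop(connectivity %*% phi(X[1, ]))
    if (!is.null(drive_fn)) inp <- inp + drive_fn(t)
    dX[1, ] <- dX[1, ] + inp
    dX
  }
  X <- with_seed(seed, rbind(matrix(stats::rnorm(N, sd = init_scale), 1),
                             matrix(0, D - 1, N)))
  n_steps <- round((burn_in + duration) / time_step)
  rec_from <- round(burn_in / time_step)
  n_rec <- floor((n_steps - rec_from) / thin) + 1L
  vars <- as.integer(record_variables)
  out <- array(NA_real_, dim = c(N, length(vars), n_rec))
  times <- numeric(n_rec)
  r <- 1L
  t <- 0
  for (step in 0:n_steps) {
    if (step >= rec_from && (step - rec_from) %% thin == 0 && r <= n_rec) {
      out[, , r] <- t(X[vars, , drop = FALSE])
      times[r] <- t - burn_in
      r <- r + 1L
    }
    if (step == n_steps) break
    k1 <- deriv(X, t)
    k2 <- deriv(X + 0.5 * time_step * k1, t + 0.5 * time_step)
    k3 <- deriv(X + 0.5 * time_step * k2, t + 0.5 * time_step)
    k4 <- deriv(X + time_step * k3, t + time_step)
    X <- X + (time_step / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + time_step
    if (anyNA(X) || any(!is.finite(X)))
      stopf("state blew up at time %g", t)
  }
  structure(list(trajectories = out, time_step = record_step, times = times,
                 burn_in = burn_in,
                 seeds = list(init = seed,
                              connectivity = attr(connectivity, "seed")),
                 parameters = list(N = N, D = D,
                                   g = attr(connectivity, "g"),
                                   duration = duration,
                                   time_step = time_step,
                                   record_step = record_step,
                                   init_scale = init_scale,
                                   drive = drive,
                                   heterogeneity = heterogeneity,
                                   model = model)),
            class = "SimulationResult")
}

#' @export
print.SimulationResult <- function(x, ...) {
  d <- dim(x$trajectories)
  cat("<SimulationResult> N =", d[1], "| variables:", d[2],
      "| samples:", d[3], "@ dt =", x$time_step, "\n")
  invisible(x)
}

#' Welch spectral estimate from simulated trajectories
#'
#' Averaged Hann-windowed periodogram over overlapping time segments and
#' over all units (units are exchangeable under the mean-field
#' description), normalized so that `df * sum(two-sided values)` equals the
#' pooled empirical variance.
#'
#' @param result a `SimulationResult`.
#' @param variable which recorded variable to analyze (default 1).
#' @param segment_length segment length in samples; rounded down to a power
#'   of two (default 2048 or the longest available).
#' @param overlap fractional overlap between segments (default 0.5).
#' @return a `Spectrum` on the grid `df = 1/(segment_length * dt)`.
#' @export
estimate_spectrum <- function(result, variable = 1L, segment_length = 2048L,
                              overlap = 0.5) {
  stopifnot(inherits(result, "SimulationResult"))
  x <- result$trajectories[, variable, ]   # N x T
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  Tn <- ncol(x)
  L <- 2^floor(log2(min(segment_length, Tn)))
  if (L < 8) stopf("trajectory too short for spectral estimation")
  step <- max(1L, floor(L * (1 - overlap)))
  starts <- seq(1L, Tn - L + 1L, by = step)
  if (length(starts) < 1) stopf("trajectory too short for one segment")
  dt <- result$time_step
  w <- 0.5 * (1 - cos(2 * pi * (0:(L - 1)) / L))      # Hann
  acc <- numeric(L)
  for (s in starts) {
    seg <- x[, s:(s + L - 1L), drop = FALSE]
    seg <- seg - rowMeans(seg)
    seg <- sweep(seg, 2, w, `*`)
    ft <- stats::mvfft(t(seg))                        # L x N
    acc <- acc + rowSums(Mod(ft)^2)
  }
  Sfull <- acc / (length(starts) * nrow(x))
  half <- Sfull[seq_len(L / 2 + 1)]
  half[2:(L / 2)] <- 0.5 * (half[2:(L / 2)] + rev(Sfull[(L / 2 + 2):L]))
  df <- 1 / (L * dt)
  # normalize to the pooled variance (Parseval with the window's power)
  v_emp <- mean((x - rowMeans(x))^2)
  half <- half / (df * (half[1] + half[L / 2 + 1] + 2 * sum(half[2:(L / 2)]))) * v_emp
  new_spectrum(half, df)
}

#' Pooled activation distribution and Gaussian comparison
#'
#' Pools the recorded activations across units and times, and reports the
#' Kolmogorov–Smirnov distance to the zero-mean Gaussian whose variance is
#' supplied (typically the mean-field prediction).
#'
#' @param result a `SimulationResult`.
#' @param variance reference Gaussian variance (default: pooled empirical
#'   variance).
#' @param breaks histogram breaks (passed to [hist()]).
#' @return list with `histogram` (a `histogram` object), `ks_distance`,
#'   `empirical_variance`, `reference_variance`.
#' @export
activation_distribution <- function(result, variance = NULL, breaks = 100) {
  stopifnot(inherits(result, "SimulationResult"))
  xs <- as.numeric(result$trajectories[, 1L, ])
  v_emp <- mean(xs^2)
  v_ref <- if (is.null(variance)) v_emp else variance
  h <- graphics::hist(xs, breaks = breaks, plot = FALSE)
  # KS distance computed directly: huge correlated samples make ks.test
  # p-values meaningless, only the D statistic is wanted
  xs_s <- sort(xs)
  n <- length(xs_s)
  Fhat <- seq_len(n) / n
  Ftheo <- stats::pnorm(xs_s, sd = sqrt(v_ref))
  D <- max(pmax(abs(Fhat - Ftheo), abs(Fhat - 1 / n - Ftheo)))
  list(histogram = h, ks_distance = D, empirical_variance = v_emp,
       reference_variance = v_ref)
}
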