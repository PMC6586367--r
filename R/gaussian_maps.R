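#' Map a Gaussian autocorrelation through the clipped-linear nonlinearity
#'
#' For a stationary zero-mean Gaussian process with autocorrelation
#' \eqn{C_x(\tau)} (variance \eqn{\sigma^2 = C_x(0)}) passed through the
#' piecewise-linear saturation \eqn{\phi_{PL}}, the output autocorrelation
#' is the Hermite series
#' \deqn{C_{\phi}( \tau) = \sigma^2 \sum_{n\ge1}
#'   \left[F^{(n-1)}(1/\sigma) - F^{(n-1)}(-1/\sigma)\right]^2
#'   \frac{\rho^n(\tau)}{n!},}
#' with \eqn{F} the standard normal cumulative distribution, \eqn{F^{(n)}}
#' its derivatives (Gaussian density and Hermite-polynomial multiples
#' thereof) and \eqn{\rho(\tau) = C_x(\tau)/C_x(0)} the normalized
#' autocorrelation. Even-`n` terms vanish because \eqn{\phi_{PL}} is odd.
#' The series is truncated adaptively: summation stops once the next term's
#' zero-lag bound falls below `1e-12` of the accumulated zero-lag value
#' (hard cap `n = 200`); since \eqn{|\rho| < 1} off zero lag, convergence is
#' geometric. The zero-lag value is replaced by the direct Gaussian
#' expectation \eqn{E[\phi_{PL}^2(x)]} computed by quadrature. Terms are
#' evaluated with a variance-normalized Hermite recurrence, so no factorials
#' or raw Hermite values are ever formed.
#'
#' @param autocorr an [new_autocorr()] object (input `C_x`).
#' @return the output `Autocorr` \eqn{C_{\phi_{PL}(x)}}.
#' @export
map_autocorr_piecewise_linear <- function(autocorr) {
  stopifnot(inherits(autocorr, "Autocorr"))
  C <- autocorr$values
  if (any(!is.finite(C))) stopf("non-finite autocorrelation")
  s2 <- C[1]
  if (s2 <= 0) return(new_autocorr(rep(0, length(C)), autocorr$lag_step))
  rho <- pmin(1, pmax(-1, C / s2))
  coef <- pl_hermite_coefficients(sqrt(s2), n_max = 200L)
  out <- numeric(length(C))
  rho_pow <- rep(1, length(C))
  acc0 <- 0
  for (n in seq_along(coef)) {
    rho_pow <- rho_pow * rho
    cn <- coef[n]
    if (cn == 0) next
    out <- out + cn * rho_pow
    acc0 <- acc0 + cn
    if (n > 2 && cn < 1e-12 * acc0) break
  }
  # zero lag from direct quadrature (exact expectation of phi_PL^2)
  out[1] <- pl_second_moment(sqrt(s2))
  new_autocorr(out, autocorr$lag_step)
}

# Series coefficients c_n = sigma^2 [F^(n-1)(1/sigma) - F^(n-1)(-1/sigma)]^2/n!
# computed via the normalized Hermite recurrence h_k = He_k/sqrt(k!).
pl_hermite_coefficients <- function(sigma, n_max = 200L) {
  x <- 1 / sigma
  dn <- stats::dnorm(x)
  coef <- numeric(n_max)
  coef[1] <- sigma^2 * (stats::pnorm(x) - stats::pnorm(-x))^2    # n = 1
  # tiny variance: the clip at |x| = 1 is never reached, phi acts as the
  # identity and only the n = 1 term survives (dnorm underflows anyway)
  if (dn == 0) return(coef[1])
  if (n_max >= 2) coef[2] <- 0                                    # even n vanish
  # h_k(x) at +x and -x, normalized: h_0 = 1, h_1 = x,
  # h_{k+1} = (x h_k - sqrt(k) h_{k-1}) / sqrt(k+1)
  hp_prev <- 1; hp <- x
  hm_prev <- 1; hm <- -x
  for (n in 3:n_max) {
    k <- n - 2L                     # Hermite order entering term n
    if (k >= 2) {
      hp_new <- (x * hp - sqrt(k - 1) * hp_prev) / sqrt(k)
      hm_new <- (-x * hm - sqrt(k - 1) * hm_prev) / sqrt(k)
      hp_prev <- hp; hp <- hp_new
      hm_prev <- hm; hm <- hm_new
    }
    if (n %% 2 == 0) { coef[n] <- 0; next }
    diff_h <- (hp - hm) * dn        # (He_k(x) - He_k(-x)) dnorm(x) / sqrt(k!)
    coef[n] <- sigma^2 * diff_h^2 / (n * (n - 1))
  }
  coef
}

# E[phi_PL(sigma Z)^2], Z standard normal: exact via truncated Gaussian
# moments, E = sigma^2 [(2 Phi(x) - 1) - 2 x dnorm(x)] + 2(1 - Phi(x)),
# x = 1/sigma. (Quadrature-free: keeps the zero lag exactly consistent with
# the series at machine precision.)
pl_second_moment <- function(sigma) {
  x <- 1 / sigma
  sigma^2 * ((2 * stats::pnorm(x) - 1) - 2 * x * stats::dnorm(x)) +
    2 * stats::pnorm(-x)
}

#' Map a Gaussian autocorrelation through a polynomial nonlinearity
#'
#' For a polynomial \eqn{\phi(x) = \sum_{j\le p} a_j x^j} the Hermite series
#' terminates:
#' \deqn{C_{\phi(x)}(\tau) = \sum_{n=1}^{p}
#'    \frac{\left(E[\phi^{(n)}(x)]\right)^2}{n!} C_x^n(\tau),}
#' with expectations over \eqn{x \sim N(0, C_x(0))}. For the cubic
#' \eqn{\phi_3(x) = x - x^3/3} this reduces to
#' \eqn{(1 + C_x^2(0) - 2C_x(0)) C_x(\tau) + \tfrac23 C_x^3(\tau)}.
#' Polynomials with a nonzero Gaussian mean \eqn{E[\phi(x)] \ne 0} are
#' rejected (the output would carry a spectral line at zero frequency that
#' the stationary zero-mean machinery does not represent).
#'
#' @param autocorr input `Autocorr`.
#' @param coefficients polynomial coefficients `a_0, a_1, ..., a_p`
#'   (degree `p >= 1`).
#' @return the output `Autocorr`.
#' @export
map_autocorr_polynomial <- function(autocorr, coefficients) {
  stopifnot(inherits(autocorr, "Autocorr"), is.numeric(coefficients),
            length(coefficients) >= 2)
  C <- autocorr$values
  s2 <- C[1]
  p <- length(coefficients) - 1L
  if (s2 <= 0) return(new_autocorr(rep(0, length(C)), autocorr$lag_step))
  if (abs(gaussian_poly_mean(coefficients, s2)) > 1e-12)
    stopf("polynomial has nonzero Gaussian mean; only zero-mean outputs are supported")
  out <- numeric(length(C))
  Cn <- rep(1, length(C))
  dcoef <- coefficients
  for (n in seq_len(p)) {
    dcoef <- poly_derivative(dcoef)
    Cn <- Cn * C
    mn <- gaussian_poly_mean(dcoef, s2)
    out <- out + mn^2 * Cn / factorial(n)
  }
  new_autocorr(out, autocorr$lag_step)
}

poly_derivative <- function(a) {
  p <- length(a) - 1L
  if (p == 0) return(0)
  a[-1] * seq_len(p)
}

# E[sum a_j x^j] for x ~ N(0, s2): odd moments vanish,
# E[x^{2m}] = s2^m (2m-1)!!.
gaussian_poly_mean <- function(a, s2) {
  j <- seq_along(a) - 1L
  even <- j %% 2 == 0
  m <- j[even] / 2
  dfact <- vapply(m, function(mm) if (mm == 0) 1 else prod(seq(1, 2 * mm - 1, by = 2)),
                  numeric(1))
  sum(a[even] * s2^m * dfact)
}

#' Map a Gaussian autocorrelation through any nonlinearity by quadrature
#'
#' Evaluates, per lag, the bivariate Gaussian expectation
#' \deqn{C_{\phi(x)}(\tau) = \iint \phi\!\left(\sqrt{C_0 - C^2(\tau)/C_0}\,u
#'   + \frac{C(\tau)}{\sqrt{C_0}}\, v\right)\phi(\sqrt{C_0}\, v)\,
#'   \mathcal{D}u\, \mathcal{D}v}
#' by nested adaptive Gauss–Kronrod quadrature (relative tolerance `1e-9`
#' per axis). Adaptive subdivision is essential here: saturating
#' nonlinearities such as the piecewise-linear unit have kinks, on which
#' fixed Gauss–Hermite rules converge only polynomially, far short of the
#' `1e-6` cross-method agreement this map is held to. The zero-lag value is
#' obtained by one-dimensional quadrature of \eqn{E[\phi^2]}.
#'
#' The cost is roughly \eqn{10^4} nonlinearity evaluations per lag, so this
#' map is intended for validation on coarse grids and as the reference for
#' the fast series map, not as the solver's inner loop.
#'
#' @param autocorr input `Autocorr`; must satisfy `|C(tau)| <= C(0)`.
#' @param nonlinearity a [nonlinearity()] specification.
#' @return the output `Autocorr`.
#' @export
map_autocorr_quadrature <- function(autocorr, nonlinearity) {
  stopifnot(inherits(autocorr, "Autocorr"),
            inherits(nonlinearity, "NonlinearitySpec"))
  C <- autocorr$values
  C0 <- C[1]
  if (C0 <= 0) return(new_autocorr(rep(0, length(C)), autocorr$lag_step))
  if (max(abs(C)) > C0 * (1 + 1e-8))
    stopf("invalid autocorrelation: |C(tau)| exceeds C(0)")
  phi <- nonlinearity$fn
  # Gaussian-weighted integrals on (-10, 10) (mass beyond is < 1e-23),
  # evaluated panel-wise so the adaptive subdivision concentrates around
  # kinks of saturating nonlinearities. Kinked integrands can still make a
  # panel report trouble at tolerances near machine precision; the value is
  # accepted whenever the summed error estimate stays far below the 1e-6
  # accuracy this map is held to.
  panels <- c(-10, -3, -1.5, -0.5, 0.5, 1.5, 3, 10)
  gauss_int <- function(f) {
    total <- 0
    err <- 0
    for (i in seq_len(length(panels) - 1L)) {
      res <- stats::integrate(f, panels[i], panels[i + 1L],
                              rel.tol = 1e-9, abs.tol = 5e-14,
                              subdivisions = 400L, stop.on.error = FALSE)
      if (res$message != "OK" && res$abs.error > 2e-8)
        stop(res$message, call. = FALSE)
      total <- total + res$value
      err <- err + res$abs.error
    }
    if (err > 1e-7) stop("quadrature error estimate too large", call. = FALSE)
    total
  }
  inner_mean <- function(s_perp, b) {
    # E_u[phi(s_perp u + b)], u ~ N(0,1); collapses to phi(b) when s_perp = 0
    if (s_perp == 0) return(phi(b))
    gauss_int(function(u) phi(s_perp * u + b) * stats::dnorm(u))
  }
  cvals <- pmin(pmax(C, -C0), C0)
  uniq <- unique(cvals)                 # lags sharing a C value share the result
  uest <- vapply(seq_along(uniq), function(i) {
    c_tau <- uniq[i]
    s_perp <- sqrt(max(C0 - c_tau^2 / C0, 0))
    tryCatch(
      gauss_int(function(vv) {
        vapply(vv, function(v) {
          phi(sqrt(C0) * v) *
            inner_mean(s_perp, (c_tau / sqrt(C0)) * v)
        }, numeric(1)) * stats::dnorm(vv)
      }),
      error = function(e)
        stopf("quadrature failed at lag with C = %g: %s", c_tau,
              conditionMessage(e)))
  }, numeric(1))
  est <- uest[match(cvals, uniq)]
  # lag 0: direct 1-D quadrature of E[phi^2]
  est[1] <- gauss_int(function(z) phi(sqrt(C0) * z)^2 * stats::dnorm(z))
  new_autocorr(est, autocorr$lag_step)
}

#' Map a spectrum through a nonlinearity by Monte-Carlo sampling
#'
#' Draws Gaussian sample paths in the frequency domain (independent complex
#' Gaussian Fourier coefficients with variance `S(f) df` per bin, Hermitian
#' symmetry), optionally adds a sinusoid `A cos(2 pi f_osc t + theta)` with
#' an independent uniform phase per sample, applies the nonlinearity
#' pointwise in the time domain, and returns the averaged periodogram.
#' Reproducible given `seed`.
#'
#' @param spectrum input `Spectrum` of the Gaussian part.
#' @param nonlinearity a [nonlinearity()] specification.
#' @param oscillatory optional `c(amplitude, frequency)`; the frequency must
#'   sit on the spectrum's grid.
#' @param n_samples number of sample paths.
#' @param seed integer seed.
#' @return the averaged output `Spectrum`.
#' @export
map_spectrum_montecarlo <- function(spectrum, nonlinearity, oscillatory = NULL,
                                    n_samples = 500L, seed = 1L) {
  stopifnot(inherits(spectrum, "Spectrum"),
            inherits(nonlinearity, "NonlinearitySpec"), n_samples >= 1)
  M <- spectrum$M
  df <- spectrum$freq_step
  dt <- 1 / (M * df)
  osc_bin <- NULL
  if (!is.null(oscillatory)) {
    A <- oscillatory[[1]]; fo <- oscillatory[[2]]
    bin <- fo / df
    if (abs(bin - round(bin)) > 1e-8 || round(bin) < 1 || round(bin) > M / 2)
      stopf("oscillatory frequency %g is not on the spectrum grid", fo)
    osc_bin <- as.integer(round(bin))
  }
  phi <- nonlinearity$fn
  tgrid <- dt * (0:(M - 1))
  with_seed(seed, {
    acc <- numeric(M)
    for (s in seq_len(n_samples)) {
      x <- gaussian_path(spectrum)
      if (!is.null(osc_bin)) {
        theta <- stats::runif(1, 0, 2 * pi)
        x <- x + A * cos(2 * pi * (osc_bin * df) * tgrid + theta)
      }
      y <- phi(x)
      acc <- acc + Mod(stats::fft(y) / M)^2 / df
    }
    Sfull <- acc / n_samples
  })
  half <- Sfull[seq_len(M / 2 + 1)]
  # fold: average the two redundant half-circles (they agree in expectation)
  half[2:(M / 2)] <- 0.5 * (half[2:(M / 2)] + rev(Sfull[(M / 2 + 2):M]))
  new_spectrum(half, df)
}

# One Gaussian time-domain sample path with the given one-sided spectrum.
# Uses the caller's RNG stream.
gaussian_path <- function(spectrum) {
  M <- spectrum$M
  df <- spectrum$freq_step
  S <- spectrum$values
  n <- length(S)                     # M/2 + 1
  c_ <- complex(M)
  c_[1] <- stats::rnorm(1) * sqrt(S[1] * df)
  c_[M / 2 + 1] <- stats::rnorm(1) * sqrt(S[n] * df)
  k <- 2:(M / 2)
  amp <- sqrt(S[k] * df / 2)
  re <- stats::rnorm(M / 2 - 1) * amp
  im <- stats::rnorm(M / 2 - 1) * amp
  c_[k] <- complex(real = re, imaginary = im)
  c_[M + 2 - k] <- Conj(c_[k])
  Re(stats::fft(c_, inverse = TRUE))
}
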