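#' Q-factor of a spectral peak
#'
#' Quality factor \eqn{Q = f_p/\Delta f_{HM}} of the stochastic
#' oscillations: the peak frequency of the power spectrum divided by its
#' full width at half maximum. The peak is located on the non-negative
#' frequency axis (the `f = 0` bin is eligible; ties break toward lower
#' frequency) and refined by parabolic interpolation; the half-maximum
#' crossings are linearly interpolated on the main lobe (the contiguous
#' region around the peak above half maximum). A spectrum whose maximum
#' sits at `f = 0` is non-resonant: `f_p = 0` and `Q` is undefined (`NA`).
#'
#' @param spectrum a `Spectrum`.
#' @return an `OscillationReport` list: `peak_frequency`, `half_max_width`,
#'   `q_factor`.
#' @export
q_factor <- function(spectrum) {
  stopifnot(inherits(spectrum, "Spectrum"))
  v <- spectrum$values
  f <- spectrum_frequencies(spectrum)
  i <- which.max(v)                      # first max: ties go to lower f
  if (i == 1L)
    return(structure(list(peak_frequency = 0, half_max_width = NA_real_,
                          q_factor = NA_real_),
                     class = "OscillationReport"))
  # parabolic refinement of the peak position
  fp <- f[i]
  if (i > 1L && i < length(v)) {
    d <- (v[i - 1] - v[i + 1]) / (2 * (v[i - 1] - 2 * v[i] + v[i + 1]))
    if (is.finite(d) && abs(d) <= 0.5) fp <- f[i] + d * spectrum$freq_step
  }
  half <- v[i] / 2
  # main lobe: walk left/right from the peak to the half-max crossings
  li <- i
  while (li > 1L && v[li - 1] > half) li <- li - 1L
  ri <- i
  while (ri < length(v) && v[ri + 1] > half) ri <- ri + 1L
  if (li == 1L && v[1] > half || ri == length(v) && v[length(v)] > half)
    stopf("no half-maximum crossing inside the grid (grid too narrow)")
  f_lo <- f[li - 1] + (half - v[li - 1]) / (v[li] - v[li - 1]) * spectrum$freq_step
  f_hi <- f[ri] + (v[ri] - half) / (v[ri] - v[ri + 1]) * spectrum$freq_step
  width <- f_hi - f_lo
  structure(list(peak_frequency = fp, half_max_width = width,
                 q_factor = fp / width),
            class = "OscillationReport")
}

#' @export
print.OscillationReport <- function(x, ...) {
  cat("<OscillationReport> f_p =", format(x$peak_frequency),
      "| FWHM =", format(x$half_max_width),
      "| Q =", format(x$q_factor), "\n")
  invisible(x)
}

#' Correlation time of an autocorrelation function
#'
#' Normalized first moment (center of mass) of the absolute
#' autocorrelation,
#' \deqn{t_c = \frac{\int_0^\infty \tau\,|C_x(\tau)|\,d\tau}
#'                  {\int_0^\infty |C_x(\tau)|\,d\tau},}
#' evaluated by the trapezoidal rule up to the last lag at which
#' \eqn{|C_x|} exceeds `floor_frac * C_x(0)`; the autocorrelation must
#' decay below that floor within the available lags.
#'
#' @param autocorr an `Autocorr`.
#' @param floor_frac truncation floor relative to `C(0)` (default `1e-4`).
#' @return the correlation time (positive scalar).
#' @export
correlation_time <- function(autocorr, floor_frac = 1e-4) {
  stopifnot(inherits(autocorr, "Autocorr"))
  C <- abs(autocorr$values)
  if (C[1] <= 0) stopf("zero-variance autocorrelation")
  floor_v <- floor_frac * C[1]
  above <- which(C > floor_v)
  horizon <- max(above)
  if (horizon == length(C))
    stopf("autocorrelation does not decay below %g * C(0) within the lag horizon",
          floor_frac)
  tau <- autocorr_lags(autocorr)[seq_len(horizon)]
  Ck <- C[seq_len(horizon)]
  pracma::trapz(tau, tau * Ck) / pracma::trapz(tau, Ck)
}

#' Split a driven spectrum into oscillatory and background components
#'
#' At the drive frequency the measured power is the sum of the chaotic
#' background and the oscillatory line. The background is estimated by
#' interpolating the neighboring bins,
#' \eqn{A_{bkg} = (S(f_I - \Delta f) + S(f_I + \Delta f))/2}, the line is
#' \eqn{A_{osc} = S(f_I) - A_{bkg}} (equivalently \eqn{b_1/\Delta f} for a
#' mean-field solution), and \eqn{\mathrm{SNR} = A_{osc}/A_{bkg}}.
#'
#' @param x a `Spectrum` (e.g. a simulation estimate) or a `DMFTSolution`
#'   carrying explicit peak coefficients.
#' @param f_I drive frequency; must sit on the grid with both neighbors
#'   inside it.
#' @return a `SignalNoiseReport` list: `A_bkg`, `A_osc`, `snr`,
#'   `snr_infinite` flag.
#' @export
split_signal_background <- function(x, f_I) {
  if (inherits(x, "DMFTSolution")) {
    df <- x$spectrum_x$freq_step
    bin <- round(f_I / df)
    if (abs(bin - f_I / df) > 1e-8) stopf("f_I = %g not on the grid", f_I)
    S <- x$spectrum_x$values
    if (bin < 1 || bin + 2 > length(S)) stopf("f_I too close to the grid edge")
    A_bkg <- (S[bin] + S[bin + 2]) / 2
    A_osc <- if (length(x$oscillatory_peaks) >= 1)
      x$oscillatory_peaks[[1]] / df
    else S[bin + 1] - A_bkg
  } else {
    stopifnot(inherits(x, "Spectrum"))
    df <- x$freq_step
    bin <- round(f_I / df)
    if (abs(bin - f_I / df) > 1e-8) stopf("f_I = %g not on the grid", f_I)
    S <- x$values
    if (bin < 1 || bin + 2 > length(S)) stopf("f_I too close to the grid edge")
    A_bkg <- (S[bin] + S[bin + 2]) / 2
    A_osc <- S[bin + 1] - A_bkg
  }
  inf_snr <- A_bkg <= 0
  structure(list(A_bkg = A_bkg, A_osc = A_osc,
                 snr = if (inf_snr) Inf else A_osc / A_bkg,
                 snr_infinite = inf_snr),
            class = "SignalNoiseReport")
}

#' @export
print.SignalNoiseReport <- function(x, ...) {
  cat("<SignalNoiseReport> A_osc =", format(x$A_osc),
      "| A_bkg =", format(x$A_bkg), "| SNR =", format(x$snr), "\n")
  if (!is.null(x$P_bkg))
    cat("  P_bkg =", format(x$P_bkg), "| P_osc =", format(x$P_osc), "\n")
  invisible(x)
}

#' Variance decomposition of a driven mean-field solution
#'
#' Splits the total variance into the background (chaotic) power
#' \eqn{P_{bkg} = \int S_{bkg}(f)\,df} and the oscillatory power
#' \eqn{P_{osc} = 2\sum_k b_k}; their sum is the total variance.
#'
#' @param solution a `DMFTSolution`.
#' @return a `SignalNoiseReport` list with `P_bkg`, `P_osc`,
#'   `total_variance`.
#' @export
variance_decomposition <- function(solution) {
  stopifnot(inherits(solution, "DMFTSolution"))
  P_bkg <- spectrum_variance(solution$spectrum_x)
  P_osc <- 2 * sum(solution$oscillatory_peaks)
  structure(list(P_bkg = P_bkg, P_osc = P_osc,
                 total_variance = P_bkg + P_osc),
            class = "SignalNoiseReport")
}
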