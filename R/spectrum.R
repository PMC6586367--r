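#' Power spectra and autocorrelations on uniform grids
#'
#' `spectrum_grid()` fixes the discrete Fourier conventions used throughout
#' the package. A spectrum is stored one-sided: values of the (even,
#' non-negative) power spectral density at `f = 0, df, ..., (M/2) df`, where
#' the implicit full circle has `M` points and `M` is a power of two so that
#' the FFT bridge to autocorrelations is exact. The paired autocorrelation is
#' stored at non-negative lags `0, dt, ..., (M/2) dt` with
#' `dt = 1/(M df)`. Discrete Parseval holds:
#' `df * sum(two-sided values) = C(0) = variance`.
#'
#' @param freq_step frequency bin `df` (default 0.001, the bin used for all
#'   mean-field solutions in the package).
#' @param max_freq requested maximum frequency; the actual grid extends to
#'   `(M/2) * df >= max_freq` with `M` a power of two.
#' @return a list with `freq_step`, `n_half` (number of stored values minus
#'   one), `M` (full circle length), `lag_step`, `max_freq`.
#' @export
spectrum_grid <- function(freq_step = 0.001, max_freq = 2) {
  stopifnot(is_scalar_num(freq_step), freq_step > 0,
            is_scalar_num(max_freq), max_freq > freq_step)
  n_half <- ceiling(max_freq / freq_step)
  M <- 2^ceiling(log2(2 * n_half))
  list(freq_step = freq_step, n_half = M / 2, M = M,
       lag_step = 1 / (M * freq_step), max_freq = (M / 2) * freq_step)
}

#' Construct a Spectrum object
#'
#' @param values non-negative values at `f = 0, df, ..., (M/2) df`
#'   (`M/2 + 1` numbers, `M` a power of two). Negative FFT round-off below
#'   `1e-12 * max` is clipped to zero.
#' @param freq_step the frequency bin `df`.
#' @return an object of class `Spectrum`.
#' @export
new_spectrum <- function(values, freq_step) {
  stopifnot(is.numeric(values), is_scalar_num(freq_step), freq_step > 0)
  M <- 2L * (length(values) - 1L)
  if (M < 2 || bitwAnd(M, M - 1L) != 0)
    stopf("spectrum must hold M/2 + 1 values with M a power of two (got %d values)",
          length(values))
  if (any(!is.finite(values))) stopf("spectrum values must be finite")
  mx <- max(values, 0)
  if (any(values < -1e-12 * max(mx, 1e-300)))
    stopf("spectrum has substantially negative values")
  values[values < 0] <- 0
  structure(list(freq_step = freq_step, values = as.numeric(values), M = M),
            class = "Spectrum")
}

#' @export
print.Spectrum <- function(x, ...) {
  cat("<Spectrum> df =", x$freq_step, "| f in [0,",
      (x$M / 2) * x$freq_step, "] |", length(x$values), "points | variance =",
      format(spectrum_variance(x)), "\n")
  invisible(x)
}

#' Construct an Autocorr object
#'
#' @param values autocorrelation at lags `0, dt, ..., (M/2) dt` (even
#'   symmetry implicit); `values[1]` is the variance and must dominate in
#'   absolute value.
#' @param lag_step the lag step `dt`.
#' @return an object of class `Autocorr`.
#' @export
new_autocorr <- function(values, lag_step) {
  stopifnot(is.numeric(values), is_scalar_num(lag_step), lag_step > 0)
  M <- 2L * (length(values) - 1L)
  if (M < 2 || bitwAnd(M, M - 1L) != 0)
    stopf("autocorr must hold M/2 + 1 values with M a power of two")
  if (any(!is.finite(values))) stopf("autocorr values must be finite")
  if (length(values) > 1 && max(abs(values[-1])) > abs(values[1]) * (1 + 1e-8) + 1e-300)
    stopf("autocorr must peak at lag zero")
  structure(list(lag_step = lag_step, values = as.numeric(values), M = M),
            class = "Autocorr")
}

#' @export
print.Autocorr <- function(x, ...) {
  cat("<Autocorr> dt =", x$lag_step, "|", length(x$values),
      "lags | C(0) =", format(x$values[1]), "\n")
  invisible(x)
}

#' Grid accessors
#'
#' `spectrum_frequencies()` and `autocorr_lags()` return the stored
#' non-negative frequency / lag grids; `spectrum_variance()` evaluates the
#' discrete Parseval sum `df * sum(two-sided values)`.
#'
#' @param x a `Spectrum` or `Autocorr`.
#' @return numeric vector (or scalar variance).
#' @export
spectrum_frequencies <- function(x) {
  stopifnot(inherits(x, "Spectrum"))
  seq(0, by = x$freq_step, length.out = length(x$values))
}

#' @rdname spectrum_frequencies
#' @export
autocorr_lags <- function(x) {
  stopifnot(inherits(x, "Autocorr"))
  seq(0, by = x$lag_step, length.out = length(x$values))
}

#' @rdname spectrum_frequencies
#' @export
spectrum_variance <- function(x) {
  stopifnot(inherits(x, "Spectrum"))
  x$freq_step * sum(two_sided(x$values))
}

# one-sided (length M/2+1) -> full circle (length M), even symmetry
two_sided <- function(v) {
  n <- length(v)
  c(v, rev(v[2:(n - 1L)]))
}

#' Fourier bridge between spectra and autocorrelations
#'
#' Discrete Wiener–Khinchin pair: `spectrum_to_autocorr()` computes
#' \eqn{C(\tau_k) = \Delta f \sum_j S_j e^{2\pi i jk/M}} and
#' `autocorr_to_spectrum()` inverts it. The round trip is the identity to
#' FFT accuracy; `C(0)` equals the spectrum's variance.
#'
#' @param spectrum a `Spectrum`.
#' @param autocorr an `Autocorr`.
#' @return the paired object.
#' @export
spectrum_to_autocorr <- function(spectrum) {
  stopifnot(inherits(spectrum, "Spectrum"))
  full <- two_sided(spectrum$values)
  C <- Re(stats::fft(full, inverse = TRUE)) * spectrum$freq_step
  n <- length(spectrum$values)
  new_autocorr(C[seq_len(n)], lag_step = 1 / (spectrum$M * spectrum$freq_step))
}

#' @rdname spectrum_to_autocorr
#' @export
autocorr_to_spectrum <- function(autocorr) {
  stopifnot(inherits(autocorr, "Autocorr"))
  full <- two_sided(autocorr$values)
  S <- Re(stats::fft(full)) * autocorr$lag_step
  mx <- max(abs(S))
  S[S < 0 & S > -1e-12 * mx] <- 0
  n <- length(autocorr$values)
  new_spectrum(S[seq_len(n)], freq_step = 1 / (autocorr$M * autocorr$lag_step))
}

#' Read and write spectra / autocorrelations as delimited text
#'
#' Two-column comma-separated files with a one-line header naming the
#' storage convention (one-sided, even symmetry implicit).
#'
#' @param x a `Spectrum` or `Autocorr`.
#' @param path file path.
#' @return `read_spectrum()` / `read_autocorr()` return the object.
#' @export
write_spectrum <- function(x, path) {
  stopifnot(inherits(x, "Spectrum"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines("frequency,value  # one-sided power spectral density, even in f", con)
  utils::write.table(data.frame(frequency = spectrum_frequencies(x),
                                value = x$values),
                     con, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  d <- utils::read.table(path, sep = ",", skip = 1)
  new_spectrum(d[[2]], freq_step = d[[1]][2] - d[[1]][1])
}

#' @rdname write_spectrum
#' @export
write_autocorr <- function(x, path) {
  stopifnot(inherits(x, "Autocorr"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines("lag,value  # one-sided autocorrelation, even in lag", con)
  utils::write.table(data.frame(lag = autocorr_lags(x), value = x$values),
                     con, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_autocorr <- function(path) {
  d <- utils::read.table(path, sep = ",", skip = 1)
  new_autocorr(d[[2]], lag_step = d[[1]][2] - d[[1]][1])
}

#' Relative L1 distance between two spectra
#'
#' The finer-resolved spectrum is linearly interpolated onto the coarser
#' grid over the overlapping frequency range; the distance is
#' `sum(|S1 - S2|) / sum(S2)` (the second argument is the reference).
#'
#' @param s1,s2 `Spectrum` objects.
#' @param f_max restrict the comparison to `f <= f_max` (default: full
#'   overlap).
#' @return non-negative scalar.
#' @export
spectrum_distance <- function(s1, s2, f_max = NULL) {
  stopifnot(inherits(s1, "Spectrum"), inherits(s2, "Spectrum"))
  if (s1$freq_step < s2$freq_step) { fine <- s1; coarse <- s2; ref_is_coarse <- TRUE }
  else { fine <- s2; coarse <- s1; ref_is_coarse <- FALSE }
  fmax <- min(max(spectrum_frequencies(s1)), max(spectrum_frequencies(s2)))
  if (!is.null(f_max)) fmax <- min(fmax, f_max)
  fc <- spectrum_frequencies(coarse)
  keep <- fc <= fmax
  fi <- stats::approx(spectrum_frequencies(fine), fine$values,
                      xout = fc[keep])$y
  a <- fi; b <- coarse$values[keep]
  ref <- if (ref_is_coarse) b else a
  sum(abs(a - b)) / sum(ref)
}
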