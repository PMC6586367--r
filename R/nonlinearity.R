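#' Static nonlinearities for rate units
#'
#' A nonlinearity specification bundles the transfer function `phi` that maps
#' the activation variable to the firing-rate deviation, together with the
#' metadata the mean-field machinery needs (kind, polynomial coefficients
#' where applicable). All admissible nonlinearities satisfy `phi(0) = 0` and
#' `phi'(0) = 1`; the stability analysis and the critical-coupling formulas
#' assume unit slope at the origin.
#'
#' Built-in kinds:
#' \describe{
#'   \item{`piecewise_linear`}{the saturating identity, clamped to
#'     \eqn{[-1, 1]}; odd, 1-Lipschitz, bounded.}
#'   \item{`cubic`}{\eqn{x - x^3/3}, the cubic approximation of tanh
#'     (unbounded).}
#'   \item{`tanh`}{the hyperbolic tangent.}
#'   \item{`custom`}{any user function with `phi(0) = 0`, `phi'(0) = 1`
#'     (checked numerically at construction, tolerance `1e-6`).}
#' }
#'
#' @param kind one of `"piecewise_linear"`, `"cubic"`, `"tanh"`, `"custom"`.
#' @param fn for `kind = "custom"`, a vectorized function of one argument.
#' @param coefficients for polynomial nonlinearities, coefficients
#'   \eqn{a_0, a_1, \ldots, a_p} of \eqn{\sum_j a_j x^j} (used by the
#'   closed-form polynomial autocorrelation map).
#' @return an object of class `NonlinearitySpec`.
#' @examples
#' pl <- nonlinearity("piecewise_linear")
#' evaluate_nonlinearity(pl, c(-3, 0.5, 2))  # -1, 0.5, 1
#' @export
nonlinearity <- function(kind = c("piecewise_linear", "cubic", "tanh", "custom"),
                         fn = NULL, coefficients = NULL) {
  kind <- match.arg(kind)
  spec <- switch(kind,
    piecewise_linear = list(kind = kind, fn = phi_pl, coefficients = NULL),
    cubic = list(kind = kind, fn = phi_cubic, coefficients = c(0, 1, 0, -1 / 3)),
    tanh = list(kind = kind, fn = tanh, coefficients = NULL),
    custom = {
      if (!is.function(fn)) stopf("custom nonlinearity requires `fn`")
      list(kind = kind, fn = fn, coefficients = coefficients)
    }
  )
  spec$deriv0 <- 1
  class(spec) <- "NonlinearitySpec"
  validate_nonlinearity(spec)
  spec
}

phi_pl <- function(x) {
  x[x > 1] <- 1
  x[x < -1] <- -1
  x
}
phi_cubic <- function(x) x - x^3 / 3

validate_nonlinearity <- function(spec) {
  f0 <- spec$fn(0)
  if (!is.finite(f0) || abs(f0) > 1e-12)
    stopf("nonlinearity must satisfy phi(0) = 0 (got %g)", f0)
  h <- 1e-6
  d0 <- (spec$fn(h) - spec$fn(-h)) / (2 * h)
  if (abs(d0 - 1) > 1e-4)
    stopf("nonlinearity must satisfy phi'(0) = 1 (numerical slope %g)", d0)
  invisible(spec)
}

#' Evaluate a nonlinearity elementwise
#'
#' @param spec a [nonlinearity()] specification.
#' @param values numeric vector.
#' @return `phi(values)`, elementwise.
#' @export
evaluate_nonlinearity <- function(spec, values) {
  stopifnot(inherits(spec, "NonlinearitySpec"))
  spec$fn(values)
}

#' @export
print.NonlinearitySpec <- function(x, ...) {
  cat("<NonlinearitySpec>", x$kind, "\n")
  invisible(x)
}

# default transfer function used throughout (avoids recursive default args)
default_nonlinearity <- function() nonlinearity("piecewise_linear")
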