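#' Hopf boundary of the adaptation model
#'
#' Curve \eqn{\beta_H(\gamma) = -1-\gamma+\sqrt{2\gamma^2+2\gamma+1}}
#' separating the saddle-node (non-resonant, \eqn{\beta \le \beta_H}) from
#' the Hopf (resonant, \eqn{\beta > \beta_H}) loss of stability of the zero
#' fixed point as the coupling `g` increases.
#'
#' @param gamma positive timescale ratio (vectorized).
#' @return \eqn{\beta_H(\gamma)}.
#' @export
hopf_beta <- function(gamma) {
  -1 - gamma + sqrt(2 * gamma^2 + 2 * gamma + 1)
}

# Closed-form critical coupling of the adaptation model; gamma = 0 allowed
# (no adaptation limit, g_c = 1 + beta restricted to beta = 0 -> 1).
critical_coupling_adaptation <- function(gamma, beta) {
  n <- max(length(gamma), length(beta))
  gamma <- rep_len(gamma, n); beta <- rep_len(beta, n)
  out <- 1 + beta                        # saddle branch
  res <- beta > hopf_beta(gamma)
  if (any(res)) {
    g <- gamma[res]; b <- beta[res]
    out[res] <- sqrt(1 - g * (g + 2 * b) + 2 * g * sqrt(b * (b + 2 * g + 2)))
  }
  out
}

#' Critical coupling strength of the random network
#'
#' The zero fixed point of the network loses stability at
#' \eqn{g_c = 1/\sqrt{\max_{f\ge 0} \tilde G(f)}}. The maximum of the squared
#' single-unit gain is located by a dense grid scan followed by bracketed
#' golden-section refinement (tolerance `1e-10`). For adaptation models the
#' closed form (resonant branch
#' \eqn{g_c^2 = 1-\gamma(\gamma+2\beta)+2\gamma\sqrt{\beta(\beta+2\gamma+2)}},
#' saddle branch \eqn{g_c = 1+\beta}) is evaluated as well and the two routes
#' are required to agree to `1e-6` relative.
#'
#' @param model a `RateModel`.
#' @param f_upper upper end of the scanned frequency range (the gain of any
#'   admissible model decays at high frequency; the default covers the
#'   regimes of interest with a wide margin).
#' @return the critical coupling \eqn{g_c} (positive scalar).
#' @examples
#' critical_coupling(adaptation_model(0.25, 1))  # ~1.1717
#' @export
critical_coupling <- function(model, f_upper = 20) {
  stopifnot(inherits(model, "RateModel"))
  mx <- max_gain(model, f_upper)
  if (!is.finite(mx$value) || mx$value <= 0)
    stopf("maximization of the squared gain failed (non-finite value)")
  gc_num <- 1 / sqrt(mx$value)
  if (is_adaptation_model(model)) {
    gc_cf <- critical_coupling_adaptation(model$gamma, model$beta)
    if (abs(gc_cf - gc_num) / gc_cf > 1e-6)
      stopf("closed-form and numeric critical couplings disagree (%g vs %g)",
            gc_cf, gc_num)
    return(gc_cf)
  }
  gc_num
}

# Dense-grid scan + golden-section refinement of max_f G(f), f >= 0.
max_gain <- function(model, f_upper = 20, n_grid = 4096) {
  fs <- seq(0, f_upper, length.out = n_grid)
  G <- gain_values(model, fs)
  i <- which.max(G)
  lo <- fs[max(1L, i - 1L)]
  hi <- fs[min(n_grid, i + 1L)]
  if (lo == hi) return(list(argmax = fs[i], value = G[i]))
  opt <- stats::optimize(function(f) gain_values(model, f),
                         lower = lo, upper = hi, maximum = TRUE,
                         tol = 1e-10)
  if (opt$objective >= G[i]) list(argmax = opt$maximum, value = opt$objective)
  else list(argmax = fs[i], value = G[i])
}

#' Resonance frequency of the adaptation model
#'
#' In the resonant regime (\eqn{\beta > \beta_H(\gamma)}) the squared gain
#' \eqn{\tilde G(f)} has its maximum at
#' \deqn{f_0 = \frac{1}{2\pi}\sqrt{-\gamma^2 +
#'       \gamma\sqrt{\beta(\beta+2\gamma+2)}},}
#' which is also the frequency of the critical eigenvalue pair at the Hopf
#' bifurcation and, empirically, the peak frequency of the chaotic power
#' spectrum for all couplings above threshold.
#'
#' @param gamma,beta adaptation parameters; must lie in the resonant regime.
#' @return \eqn{f_0} (positive scalar; 0 exactly on the boundary).
#' @export
resonance_frequency <- function(gamma, beta) {
  if (!is_scalar_num(gamma) || gamma <= 0) stopf("gamma must be > 0")
  if (!is_scalar_num(beta) || beta < 0) stopf("beta must be >= 0")
  rad <- -gamma^2 + gamma * sqrt(beta * (beta + 2 * gamma + 2))
  if (beta < hopf_beta(gamma))
    stopf("f_0 undefined: parameters are in the non-resonant regime (beta <= beta_H)")
  sqrt(max(rad, 0)) / (2 * pi)
}

#' Classify the dynamical regime of an adaptation network
#'
#' @param gamma,beta adaptation parameters (`gamma > 0`, `beta >= 0`).
#' @return a `StabilityReport` list: `critical_coupling`, `regime`
#'   (`"resonant"` or `"non_resonant"`), `hopf_boundary_beta`,
#'   `resonance_frequency` (`f_0`; 0 in the non-resonant regime) and
#'   `argmax_gain` (numeric argmax of \eqn{\tilde G}).
#' @examples
#' classify_regime(0.2, 0.5)$regime  # "resonant"
#' @export
classify_regime <- function(gamma, beta) {
  model <- adaptation_model(gamma, beta)
  bH <- hopf_beta(gamma)
  resonant <- beta > bH
  mx <- max_gain(model)
  structure(list(
    critical_coupling = critical_coupling(model),
    regime = if (resonant) "resonant" else "non_resonant",
    hopf_boundary_beta = bH,
    resonance_frequency = if (resonant) resonance_frequency(gamma, beta) else 0,
    argmax_gain = mx$argmax,
    gamma = gamma, beta = beta
  ), class = "StabilityReport")
}

#' @export
print.StabilityReport <- function(x, ...) {
  cat("<StabilityReport> gamma =", x$gamma, ", beta =", x$beta, "\n",
      " regime:", x$regime, "| g_c =", format(x$critical_coupling),
      "| beta_H =", format(x$hopf_boundary_beta),
      "| f_0 =", format(x$resonance_frequency), "\n")
  invisible(x)
}

#' Jacobian eigenvalues from a connectivity eigenvalue
#'
#' In the large-`N` limit the eigenvalues of the network Jacobian at the
#' zero fixed point are the image of the eigenvalues \eqn{\lambda_J} of the
#' connectivity matrix (uniform on the disk of radius `g`) under the
#' inverse of the rational map
#' \deqn{\lambda_J = \frac{\prod_i (\lambda_B - \lambda_{A,i})}
#'                        {\prod_j (\lambda_B - \lambda_{A^-,j})},}
#' where \eqn{A^-} is `A` with its first row and column removed. For the
#' adaptation model the inverse is the closed form
#' \eqn{\lambda_B = \tfrac12(\lambda_J - 1 - \gamma \pm
#' \sqrt{(\lambda_J-1+\gamma)^2-4\gamma\beta})}. For general `D` the
#' inversion is performed exactly by eigendecomposition of the rank-one
#' update \eqn{A + \lambda_J e_1 e_1^T} (the per-eigenvalue block of the
#' similarity-transformed network Jacobian); this route has no excluded
#' set, and in particular handles the removable singularities of the
#' rational map (roots coincident with eigenvalues of \eqn{A^-}) exactly.
#'
#' @param model a `RateModel`.
#' @param connectivity_eigenvalue a complex scalar \eqn{\lambda_J}.
#' @return complex vector of the `D` Jacobian eigenvalues.
#' @export
jacobian_eigenvalues <- function(model, connectivity_eigenvalue) {
  stopifnot(inherits(model, "RateModel"), length(connectivity_eigenvalue) == 1L)
  lJ <- as.complex(connectivity_eigenvalue)
  if (is_adaptation_model(model)) {
    g <- model$gamma; b <- model$beta
    disc <- sqrt(as.complex((lJ - 1 + g)^2 - 4 * g * b))
    return(0.5 * c(lJ - 1 - g + disc, lJ - 1 - g - disc))
  }
  D <- model$dim
  M <- model$interaction + diag(0i, D)
  M[1, 1] <- M[1, 1] + lJ
  eigen(M, only.values = TRUE)$values
}

# Forward map lambda_B -> lambda_J (Jacobian eigenvalue to connectivity
# eigenvalue), vectorized over lambda_B.
connectivity_eigenvalue <- function(model, lambda_B) {
  lA <- model$eigenvalues
  lAm <- if (model$dim > 1)
    eigen(model$interaction[-1, -1, drop = FALSE], only.values = TRUE)$values
  else complex(0)
  vapply(as.complex(lambda_B), function(lB) {
    num <- prod(lB - lA)
    den <- prod(lB - lAm)
    num / den
  }, complex(1))
}

#' Finite-network Jacobian spectrum
#'
#' Assembles the `ND x ND` Jacobian of the coupled network at the zero
#' fixed point (with `phi'(0) = 1`), i.e. the block matrix with blocks
#' \eqn{A^{\alpha\beta} I_N + \delta^{\alpha 1}\delta^{\beta 1} J}, and
#' returns its eigenvalues.
#'
#' @param model a `RateModel`.
#' @param connectivity an `N x N` connectivity matrix (see
#'   [sample_connectivity()]).
#' @param max_size refuse problems with `N * D` above this cap.
#' @return complex vector of `N * D` eigenvalues.
#' @export
finite_jacobian_spectrum <- function(model, connectivity, max_size = 4000L) {
  stopifnot(inherits(model, "RateModel"), is.matrix(connectivity),
            nrow(connectivity) == ncol(connectivity))
  N <- nrow(connectivity); D <- model$dim
  if (N * D > max_size)
    stopf("refusing eigendecomposition of size %d > cap %d; raise max_size if intended",
          N * D, max_size)
  B <- kronecker(model$interaction, diag(N))
  B[seq_len(N), seq_len(N)] <- B[seq_len(N), seq_len(N)] + connectivity
  eigen(B, only.values = TRUE)$values
}
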