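---
title: "Resonant chaos in random rate networks: models, solver, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resonant chaos in random rate networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratechaos)
```

## The model

Each of $N$ units carries $D$ variables $x^1,\dots,x^D$; the first is the
activation whose nonlinear transform $\phi(x^1)$ is the unit's output-rate
deviation from a reference (so it is signed), and the remaining $D-1$ are
auxiliary internal variables:

$$\dot x_i^\alpha = \sum_\beta A^{\alpha\beta} x_i^\beta +
  \delta^{\alpha 1}\Big(\textstyle\sum_j J_{ij}\,\phi(x_j^1) + I_i(t)\Big),
  \qquad J_{ij} \sim N(0, g^2/N).$$

Time is dimensionless (the timescale of $x^1$ is 1). The interaction matrix
$A$ must be non-singular with eigenvalues strictly in the left half plane:
an isolated unit is stable. The leading instance is spike-frequency
adaptation, a slow negative feedback $a$ with timescale ratio $\gamma$ and
strength $\beta$:

$$\dot x = -x - a + \mathrm{input}, \qquad \dot a = -\gamma a + \gamma\beta x,$$

i.e. `adaptation_model(gamma, beta)` with
$A = \begin{pmatrix} -1 & -1\\ \gamma\beta & -\gamma\end{pmatrix}$.
The default transfer function is the clipped-linear unit
$\phi_{PL}(x) = \max(-1, \min(1, x))$; a cubic ($x - x^3/3$), `tanh`, and
arbitrary user functions with $\phi(0)=0$, $\phi'(0)=1$ are also supported
(the unit slope at the origin is assumed by all stability formulas and is
enforced at construction).

## What the single unit contributes: $\tilde G(f)$

All single-unit structure enters through one function, the squared modulus
of the linear response of an uncoupled unit,
$\tilde G(f) = \big|[(2\pi i f I_D - A)^{-1}]_{11}\big|^2$. For adaptation,

$$\tilde G(f) = \frac{\gamma^2 + \omega^2}
  {\omega^4 + (1+\gamma^2-2\beta\gamma)\,\omega^2 + \gamma^2(1+\beta)^2},
  \qquad \omega = 2\pi f .$$

Two regimes follow from the shape of $\tilde G$. Below the Hopf boundary
$\beta_H(\gamma) = -1-\gamma+\sqrt{2\gamma^2+2\gamma+1}$ the gain is
low-pass and the network loses stability through a real eigenvalue
(saddle-node); above it $\tilde G$ is band-pass with a maximum at

$$f_0 = \frac{1}{2\pi}\sqrt{-\gamma^2 +
  \gamma\sqrt{\beta(\beta+2\gamma+2)}},$$

and the instability is a Hopf bifurcation at that frequency. The critical
coupling is fixed by $g_c^2 \max_f \tilde G(f) = 1$; for adaptation it has
the closed form (resonant branch)
$g_c^2 = 1-\gamma(\gamma+2\beta)+2\gamma\sqrt{\beta(\beta+2\gamma+2)}$ and
(saddle branch) $g_c = 1+\beta$. The printed rendering of the resonant
branch in circulation is typographically ambiguous; the implementation
treats the implicit condition $g_c^2\max\tilde G = 1$ as ground truth and
`critical_coupling()` cross-checks the closed form against the numerical
maximization (golden-section refinement, tolerance $10^{-10}$) on every
call, erroring if they disagree beyond $10^{-6}$ relative. Adaptation is
always stabilizing: $g_c > 1$ for $\gamma,\beta > 0$.

```{r stability}
classify_regime(0.25, 1)
```

For the eigenvalue geometry, the network Jacobian at the origin
block-diagonalizes over the eigenvalues $\lambda_J$ of $J$ (uniform on the
disk of radius $g$ in the large-$N$ limit); per $\lambda_J$ the $D$
Jacobian eigenvalues are those of the rank-one update
$A + \lambda_J e_1 e_1^T$. We compute them by direct eigendecomposition of
that $D\times D$ matrix rather than by rooting the equivalent rational map:
the two are identical where the map is defined, but the eigendecomposition
also handles the map's removable singularities (e.g. $\beta = 0$) without
special-casing. For $D = 2$ the closed form
$\lambda_B = \tfrac12\big(\lambda_J - 1 - \gamma \pm
\sqrt{(\lambda_J-1+\gamma)^2 - 4\gamma\beta}\big)$ is used.

## The self-consistent mean-field solver

For large $N$ the input to a unit is a zero-mean Gaussian process $\eta$
with $S_\eta = g^2 S_{\phi(x)}$, and the stationary power spectrum of the
activation solves the fixed-point equation

$$S_x(f) = \tilde G(f)\,\big(g^2 S_{\phi(x)}(f) + S_I(f)\big).$$

`solve_dmft()` iterates a linear step (multiplication by
$g^2\tilde G$) and a nonlinear step ($S_x \mapsto S_{\phi(x)}$, see below),
starting from a constant (white) rate spectrum. The white start's level is
arbitrary; it defaults to unit variance and the test suite verifies that
the fixed point does not depend on it. Below $g_c$ the iteration contracts
to the zero spectrum (quiescence); above $g_c$ it converges to the
continuous spectrum of the chaotic phase, whose peak stays at $f_0$ for all
couplings — the recurrent network *sharpens* the single-unit response
without moving its preferred frequency. `sharpening_iterates()` exposes the
mechanism: iterate $n$ is approximately proportional to $\tilde G^n$ for
small $n$ (exactly $\tilde G$ at $n=1$).

Numerical choices, all configurable via `solver_config()`:

* **Grid.** One-sided storage on $f \in [0, f_{\max}]$ with bin
  $\Delta f = 0.001$ and $f_{\max} = 2$ by default; the implicit full
  circle is rounded up to a power of two ($M = 4096$) so that the
  spectrum–autocorrelation bridge is a plain FFT pair
  (`spectrum_to_autocorr()` / `autocorr_to_spectrum()`), with
  $\Delta f\sum S$ equal to the variance by construction. $f_{\max} = 2$
  covers roughly $20 f_0$ for the adaptation regimes studied, so harmonic
  content is not clipped.
* **Convergence.** Relative $L^1$ change of $S_x$ below $10^{-6}$; the
  zero solution is declared when $\max_f S_x < 10^{-10}$ (the sub-critical
  iteration decays geometrically and never meets a relative criterion).
* **Damping.** Update $S \leftarrow (1-\alpha)S + \alpha S_{\rm new}$ with
  $\alpha = 1$; if the residual sequence alternates, $\alpha$ is halved
  (floor 0.25). Plain iteration can ping-pong near criticality.
* **Initial level.** Variance 1; tested to be immaterial.

```{r solve}
m <- adaptation_model(0.25, 1)
gc <- critical_coupling(m)
sol <- solve_dmft(m, 2 * gc)
sol
q_factor(sol$spectrum_x)
```

## Nonlinearity maps for Gaussian processes

The nonlinear step needs $C_{\phi(x)}$ as a functional of $C_x$ for a
stationary Gaussian $x$. Four interchangeable routes are implemented and
cross-validated against each other (deterministic pairs to $10^{-6}$,
Monte-Carlo within sampling error); this mutual agreement is the module's
central oracle.

1. **Hermite series for the clipped unit**
   (`map_autocorr_piecewise_linear()`):
   $C_\phi(\tau) = \sigma^2\sum_{n\ge1}
   [F^{(n-1)}(1/\sigma) - F^{(n-1)}(-1/\sigma)]^2\rho^n(\tau)/n!$ with
   $\sigma^2 = C_x(0)$, $\rho = C_x/\sigma^2$, $F$ the standard normal
   CDF. Two source-text ambiguities were resolved by derivation and
   oracle: the series argument must be the *normalized* correlation
   $\rho^n$ (the literal unnormalized reading contradicts the adjacent
   closed form's $n=1$ coefficient
   $\mathrm{Erf}^2(1/\sqrt{2C_x(0)})$), and the $1/n!$ present in the
   general Hermite expansion is kept. Terms are computed with a
   variance-normalized Hermite recurrence $h_k = He_k/\sqrt{k!}$, so
   neither factorials nor raw Hermite values are ever formed (both
   overflow near the $n = 200$ cap); truncation stops when a term's
   zero-lag bound falls below $10^{-12}$ of the accumulated value. The
   zero lag uses the exact truncated-Gaussian moment
   $E[\phi_{PL}^2] = \sigma^2[(2\Phi(x)-1) - 2x\varphi(x)] + 2\Phi(-x)$,
   $x = 1/\sigma$ — closed-form rather than numerical, because even a
   $10^{-9}$-level inconsistency at lag zero injects a white floor that
   turns the far tails of sharply peaked spectra negative.
2. **Closed polynomial sum** (`map_autocorr_polynomial()`): for
   polynomial $\phi$ the series terminates at the degree; for the cubic it
   reduces to $(1 + C_0^2 - 2C_0)C + \tfrac23 C^3$.
3. **Bivariate quadrature** (`map_autocorr_quadrature()`), the generic
   route: per lag the two-dimensional Gaussian expectation is evaluated by
   *nested adaptive Gauss–Kronrod* integration (relative tolerance
   $10^{-9}$ per axis). Fixed Gauss–Hermite rules were evaluated and
   rejected: for kinked saturations the successive-order differences
   plateau near $10^{-4}$ even at order 2048, far from the $10^{-6}$
   cross-method tolerance, whereas adaptive subdivision isolates the
   kinks. At roughly $10^4$ function evaluations per lag this map is the
   validation reference, not the solver's inner loop.
4. **Monte-Carlo** (`map_spectrum_montecarlo()`): Hermitian complex
   Gaussian Fourier coefficients with per-bin variance $S(f)\Delta f$,
   optional added sinusoid with a uniform phase per sample, $\phi$ applied
   pointwise in time, averaged periodogram back. Seeded and bit-exact
   reproducible.

## Oscillatory drive, SNR, and chaos suppression

With drive $I_i = A_I\cos(2\pi f_I t + \theta_i)$, $\theta_i$ uniform, the
input spectrum is a line of one-sided mass $A_I^2/4$ at $f_I$ and the
stationary activation splits into a Gaussian background plus spectral
lines $b_k$ at harmonics $k f_I$ (`solve_dmft_driven()`). A closure choice
arises that the printed equations do not fix: how the periodic component
re-enters through the recurrent term. Because both $J_{ij}$ and the drive
phases are independent across units, the periodic power a unit receives
from the network is incoherent with its own drive phase (the coherent part
is $O(1/\sqrt N)$); the lines must therefore close in *power*,

$$b_k \leftarrow \tilde G(k f_I)\big(g^2 b_k^{\phi} +
  \delta_{k1} A_I^2/4\big),$$

not in complex amplitude. (The amplitude-coherent closure was implemented
first and rejected against microscopic simulation: it lets weak drive ride
the full loop gain $g^2\tilde G > 1$, growing until saturation and wrongly
extinguishing the chaotic background at $A_I = 0.5$.) Two further
estimator choices inside the Monte-Carlo nonlinear step matter:

* the unit's own-drive line has deterministic amplitude, but the line
  power arriving through the random network is a complex-Gaussian phasor
  across units; each sample path therefore receives the direct line at
  fixed amplitude plus network lines with Rayleigh-distributed amplitudes
  drawn from $CN(0, b_k^{net})$. Injecting the full mean power at fixed
  amplitude overstates the (power-concave) nonlinear transmission and
  again inflates the resonant loop;
* the transmitted line mass is estimated by passing the *same* line
  phasors through two independent background sample paths and averaging
  the cross-periodogram at the harmonic bin — the independent background
  contributions cancel in expectation, leaving exactly the coherent line
  power. Reading the line off a single averaged periodogram as the excess
  over the interpolated neighbors is biased wherever the background is
  curved; when $f_I$ sits on the chaotic resonance, the iteration
  amplifies that curvature excess into a spuriously strong line and a
  blurred signal-to-noise minimum. With the cross-periodogram estimator
  the solved fundamental line mass matches a leakage-free on-bin
  measurement from a matched microscopic network to a few percent.

For *reported* spectra, the background/oscillation split of
`split_signal_background()` uses the printed neighbor-interpolation rule
$A_{bkg} = \big(S(f_I-\Delta f)+S(f_I+\Delta f)\big)/2$,
$A_{osc} = b_1/\Delta f$, SNR $= A_{\rm osc}/A_{\rm bkg}$, and the
variance decomposition is
$\mathrm{Var}(x) = P_{\rm bkg} + 2\sum_k b_k$. Because the step is
stochastic, residuals are judged on a 5-iteration moving average (default
tolerance $2\times10^{-2}$; use $\le 10^{-3}$ when the suppressed-chaos
tail matters) and the reported solution averages the last iterates. Two
practical notes from validating against matched microscopic runs: at
$A_I = 0.5$ the SNR$(f_I)$ valley around $f_0$ has a flat bottom relative
to the solver's Monte-Carlo noise, so locating its minimum robustly calls
for a smooth (e.g. quadratic) fit across the resonance region rather than
a raw argmin; and at $A_I = 1.5$ near $f_0$ the background is suppressed
strongly but not totally ($P_{\rm bkg}/P_{\rm osc} \approx 0.1$ in both
solver and simulation at $N = 1000$).

Below criticality the picture is linear
(`linear_response_prediction()`): signal and external noise are shaped by
the same susceptibility $|\tilde\chi_\beta|^2 = \tilde G/(1-g^2\tilde G)$,
so $\mathrm{SNR}(f_I) = A_I^2/(4 S_\eta(f_I)\Delta f)$ — independent of the
unit parameters. Above criticality the noise is internally generated with
the resonant spectrum, so the SNR inherits a *notch* at $f_0$ and is
largest for slow signals: adaptation shapes signal transmission only in
the chaotic phase. Strong drive near $f_0$ suppresses the background
entirely ($P_{\rm bkg} \to 0$): entrainment into a limit cycle.

Heterogeneous adaptation strength ($\beta_i \sim N(\bar\beta,
\sigma_\beta^2)$, quenched) is handled at the level of the effective
filter $\tilde G_H = \tilde G/\big(1 -
\tfrac{\gamma^2\sigma_\beta^2}{\gamma^2+\omega^2}\tilde G\big)$
(`heterogeneous_gain()`, `solve_dmft_heterogeneous()`), which raises power
only at low frequencies. The full per-unit heterogeneous mean-field system
is exercised only through the microscopic simulator
(`integrate_network(..., heterogeneity = beta_i)`), since the
effective-filter deviations are below the theory–simulation mismatch of
the homogeneous case and cannot be verified more finely. Negative sampled
$\beta_i$ are used as drawn (faithful to the Gaussian sampling), with a
logged warning and their fraction reported.

## The microscopic simulator as empirical oracle

`integrate_network()` integrates the full $N\!\times\!D$ system with a
fixed-step classical Runge–Kutta scheme. Choices the source material does
not fix, made once here:

* step $\Delta t = 0.05$, guarded by a precondition
  ($\Delta t \le 0.1\times$ the fastest timescale of $A$) and by a
  step-halving test that bounds the spectral effect of $\Delta t$ by the
  estimator's own resampling error;
* burn-in 200 time units, default duration 2000 (post-burn-in), initial
  $x_i \sim N(0, 0.5^2)$, $a_i = 0$;
* recording thinned to 0.25 time units (Nyquist 2, matching the solver
  grid's reach);
* named, independently seeded streams for connectivity, initial
  conditions, drive phases and heterogeneity, so each randomness source
  can be frozen separately;
* spectra estimated by Hann-windowed Welch averaging with 50% overlap,
  over segments *and* over units (exchangeable under the mean-field
  assumption), renormalized to the empirical variance;
* `activation_distribution()` pools $x$ over units and times and reports
  the Kolmogorov–Smirnov distance to the zero-mean Gaussian with the
  mean-field variance. The D statistic is computed directly: with $10^6$+
  correlated samples, test p-values would be meaningless and only the
  distance is scientifically relevant.

What the simulator does and does not emulate: it is the finite-$N$ truth
for everything the theory predicts (spectra, distributions, thresholds,
drive responses), but at desk scale ($N$ in the hundreds to low
thousands, durations $\lesssim$ 2000) single-realization periodograms
carry bin-level noise that argmax-type statistics inherit. Tests therefore
compare band powers and power-weighted peak centroids where a raw argmax
would be dominated by realization noise. Agreement of these scaled-down
runs with the mean-field solution supports the theory near the studied
parameter sets; it does not establish finite-size convergence rates, and
all figures of merit degrade close to $g_c$ where finite-size effects are
largest.

## Problem sizes used by the validation suite

The packaged checks run the solver at $\Delta f = 0.001$ (production grid)
for threshold, peak-invariance and monotonicity properties; driven-solver
scans use 96 Monte-Carlo path pairs per iteration; microscopic comparisons
use $N = 1000$ units for 2000 time units (spectrum) and $N = 2000$ for 500
time units (activation distribution), integrated with step 0.1 (inside the
step guard; the step-halving check bounds the spectral effect). At these
sizes the pooled activation distribution and the total variance match the
mean-field prediction tightly, while the single-realization periodogram
retains a finite-size excess at the spectral peak, whose position scatters
across connectivity draws — pointwise spectral distances therefore bottom
out well above the variance-level agreement, and the suite reports both
comparisons separately. The near-critical solve at $g = 1.05\,g_c$ is the
slowest (critical slowing of the fixed-point iteration) and is capped at
3000 iterations.

## Known limitations

* The solver asserts nothing about uniqueness of the nonzero fixed point;
  it reports convergence and the fixed-point residual.
* The sharpening description $(\tilde G)^n$ is a first-order account valid
  for the first few iterations only; it is exposed for inspection, not
  used for solving.
* Maximum Lyapunov exponents are not computed; "chaos" is diagnosed
  spectrally (continuous nonzero spectrum), as in the underlying theory.
* The driven solver tracks harmonics as independent-phase lines; any
  residual cross-harmonic phase structure of the microscopic dynamics is
  outside its state space.
* The $g \to \infty$ limit and codimension-two (Bogdanov–Takens) analyses
  are out of scope beyond regime classification.
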