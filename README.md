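# ratechaos

Dynamical mean-field analysis of large random networks of
multi-dimensional rate neurons — with spike-frequency adaptation as the
worked-out case — for computational neuroscientists studying how
single-cell dynamics shape network-level chaos and signal transmission.

Each of `N` units carries `D` variables; the first, the activation `x¹`,
couples to the others through random Gaussian weights
`J_ij ~ N(0, g²/N)` after passing through a saturating nonlinearity
`φ` (`φ(0) = 0`, `φ'(0) = 1`):

    dxᵅ/dt = Σ_β A^{αβ} xᵝ + δ^{α1} ( Σ_j J_ij φ(x_j¹) + I(t) )

For adaptation, `A = [[-1, -1], [γβ, -γ]]`: an auxiliary variable `a`
feeds back negatively on `x` with timescale ratio `γ` and strength `β`.
Everything the single unit contributes is condensed into the squared gain
`G̃(f) = |[(2πif·I − A)⁻¹]₁₁|²`:

* the zero fixed point destabilizes at the **critical coupling**
  `g_c = 1/√(max_f G̃)`; adaptation always raises it above 1;
* for `β > β_H(γ) = −1−γ+√(2γ²+2γ+1)` the gain is band-pass with peak
  `f₀ = (1/2π)√(−γ² + γ√(β(β+2γ+2)))` and the instability is a Hopf
  bifurcation — above `g_c` the network enters **resonant chaos**, a
  chaotic state whose power spectrum is a sharpened copy of `G̃`
  peaked exactly at `f₀`;
* the chaotic spectrum solves the self-consistent mean-field equation
  `S_x(f) = G̃(f)(g² S_φ(x)(f) + S_I(f))`, which the package solves by
  fixed-point iteration with semi-analytic Hermite-series, polynomial,
  quadrature or Monte-Carlo treatments of the nonlinear step
  `S_x → S_φ(x)`.

On top of the solver: Jacobian spectra for finite networks and the
`N → ∞` disk image, oscillatory drive with harmonic line bookkeeping and
signal-to-noise analysis, quenched heterogeneity of `β` via an effective
filter, a seeded Runge–Kutta microscopic simulator as empirical oracle,
and spectral metrics (Q-factor, correlation time, variance
decomposition).

## Worked example

```r
library(ratechaos)

m <- adaptation_model(gamma = 0.25, beta = 1)
classify_regime(0.25, 1)
#> <StabilityReport> gamma = 0.25 , beta = 1
#>  regime: resonant | g_c = 1.171714 | beta_H = 0.02475488 | f_0 = 0.1013115

gc <- critical_coupling(m)
sol <- solve_dmft(m, 2 * gc)       # chaotic phase, g = 2 g_c
sol
#> <DMFTSolution> g = 2.343429 | nonzero (chaotic) solution
#>   iterations: 143 | converged: TRUE | variance: 2.34301

q_factor(sol$spectrum_x)
#> <OscillationReport> f_p = 0.1016353 | FWHM = 0.04064977 | Q = 2.500268
```

The report says: at these adaptation parameters the isolated neuron is a
band-pass filter peaking at `f₀ ≈ 0.101` (in units of the inverse
membrane timescale), the network destabilizes at `g_c ≈ 1.17`, and at
twice that coupling the chaotic activity has variance ≈ 2.34 with a
spectral peak at `f_p ≈ 0.102 ≈ f₀` whose quality factor ≈ 2.5 exceeds
that of a single white-noise-driven unit — the recurrent connectivity has
sharpened, not shifted, the single-neuron resonance.

A microscopic check against the mean-field solution:

```r
J <- sample_connectivity(1000, 2 * gc, seed = 1)
res <- integrate_network(m, J, duration = 2000, seed = 2)
sp <- estimate_spectrum(res)
spectrum_distance(sp, sol$spectrum_x, f_max = 0.5)   # relative L1
```

## Command line

A thin front end over the same functions lives at
`inst/scripts/ratechaos`:

```sh
Rscript inst/scripts/ratechaos stability --gamma 0.25 --beta 1 --out out/
Rscript inst/scripts/ratechaos solve --gamma 0.25 --beta 1 --g 2.34 --out out/
```

Subcommands: `stability`, `solve`, `simulate`, `signal-scan`, `metrics`,
`fixtures`. Every flag overrides its YAML config key; all outputs (CSV
tables, JSON reports) carry a verbatim config echo and are bit-identical
across reruns with the same seed.

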