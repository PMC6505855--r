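# sirews

Critical slowing down and early-warning signals for epidemic transitions in
the stochastic SIR model with vaccination.

## The problem

Re-emergence of vaccine-preventable diseases (and elimination campaigns run
in reverse) can be framed as a *critical transition*: as vaccine uptake
ν drifts toward the immunization threshold ν<sub>c</sub> = 1 − 1/R₀, the
dominant eigenvalue of the endemic equilibrium approaches zero, perturbations
dissipate ever more slowly, and measurable statistics of surveillance-like
time series — variances, autocorrelations, oscillation periods — change in
characteristic ways *before* the threshold is crossed. `sirews` implements
the full chain needed to study this quantitatively, for epidemiologists and
modellers who want to prototype early-warning indicators against a fully
specified stochastic benchmark:

1. **Deterministic skeleton** — equilibria of the birth–death SIR model with
   vaccination at birth and low-rate case importation ("sparking" η);
   Jacobians; the damped-oscillator reading of the linearization
   (z̈ − τż + Δz = 0 with τ = tr **J**, Δ = det **J**); damping ratio
   ζ = −τ/√(4Δ); potential wells V(z) = Δz²/2; the endemic eigenvalues
   −μR₀(1−ν)/2 ± √((μR₀(1−ν))²/4 − μ(R₀(1−ν)−1)(μ+γ)); the inter-epidemic
   period 2π√(AD).
2. **Fluctuation theory** — demographic-noise diffusion matrix, stationary
   covariance Σ from the Lyapunov equation **J**Σ + Σ**J**ᵀ + **B** = 0,
   generalized variance det Σ, 95% concentration ellipses, lagged
   autocovariance e^{**J**ℓ}Σ.
3. **Simulators** — exact event-driven (Gillespie, compiled core),
   Euler–Maruyama diffusion, exact Ornstein–Uhlenbeck sampling of the
   linearization, and noise-free ODE runs, all supporting time-varying
   vaccine-uptake schedules.
4. **Estimators** — rolling-window variance/generalized variance/lag
   autocorrelation, damped-oscillation fits of the ACF, amplitude recovery
   rates λ = d ln r/dt, and inversion of the eigenvalue-modulus identity
   |λ|² = μ(μ+γ)[R₀(1−ν)−1] into a distance-to-threshold estimate.

Everything is tibble-in/tibble-out with `tidy()`/`glance()` methods and
`autoplot()`/`plot_*()` figures.

## Worked example

The default parameter set is a measles-like infection: b = 2×10⁵/y,
μ = 0.02/y (N = 10⁷), γ = 365/22/y, η = 2×10⁻⁵/y, R₀ = 17.

```r
library(sirews)

p <- sir_params()
threshold_uptake(p)
#> [1] 0.9411765
underdamped_boundary(p)
#> [1] 0.93894
```

Vaccinating 94.1% of births stops sustained transmission; already at 93.9%
uptake the endemic equilibrium's damping ratio crosses one and perturbations
return through slow, overshooting oscillations — the window where critical
slowing down is visible in the dynamics.

```r
glance(stability(set_uptake(p, 0.9)))
#> # A tibble: 1 × 9
#>   branch        S     I     tau Delta   zeta modulus period regime
#>   <chr>     <dbl> <dbl>   <dbl> <dbl>  <dbl>   <dbl>  <dbl> <chr>
#> 1 sparked 587398.  497. -0.0577 0.234 0.0597   0.484   13.0 stable underdamped
```

At 90% uptake the equilibrium holds ~497 infecteds, and perturbations spiral
back with a 13-year period. The estimator layer reads those eigenvalues back
out of simulated data:

```r
p5  <- set_uptake(p, 0.5)
st  <- stability(p5)
z   <- ou_sample(st$J, diffusion_matrix(p5), T = 200, dt = 1 / 52, seed = 1)
ac  <- acf_curve(z, max_lag = 12)
fit <- fit_damped_oscillation(data.frame(lag = ac$lag, value = ac$acf_I))
tidy(fit)
#> # A tibble: 1 × 6
#>   damping frequency  phase period   rss overdamped
#>     <dbl>     <dbl>  <dbl>  <dbl> <dbl> <lgl>
#> 1   0.135      1.59 0.0230   3.95 0.681 FALSE

distance_to_threshold(fit$damping, fit$frequency, p$mu, p$gamma)
#> # A tibble: 1 × 2
#>   distance below_threshold
#>      <dbl> <lgl>
#> 1     7.69 TRUE
```

From 200 years of weekly fluctuation data the fitted ACF frequency and
damping invert to a distance estimate of 7.69 for a true
R₀(1 − ν) − 1 = 7.5 — a 2.5% error with no knowledge of the simulation
settings beyond μ and γ.

A command-line interface wraps the same functions
(`inst/exec/sirews theory|simulate|ews|fixtures`), e.g.

```sh
Rscript inst/exec/sirews theory --R0 17 --b 2e5 --mu 0.02 --gamma 16.5909 --eta 2e-5 --out theory.csv
Rscript inst/exec/sirews simulate --method gillespie --b 2e3 --nu 0.5 --T 50 --seed 1 --out run.csv
Rscript inst/exec/sirews ews --input run.csv --window 10 --lag 1 --out ews.csv
```

See `vignettes/critical-slowing-down.Rmd` for the model assumptions,
numerical conventions, and known limitations (in particular where the
linear-noise prediction for Var(I) stops being quantitative).

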