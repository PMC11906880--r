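# ddex — double diffusion encoding, water exchange and transient kurtosis

Diffusion MRI with double diffusion encoding (DDE) is read in two competing
ways. Correlation tensor imaging (CTI) decomposes the diffusional kurtosis
into isotropic, anisotropic and *microscopic* parts, estimating the
microscopic kurtosis K<sub>μ</sub> from the contrast between single
diffusion encoding (SDE) and parallel DDE at the same b-value. Multi-Gaussian
exchange (MGE) reads the *same* contrast as water exchange between
compartments at rate k, weighted by a waveform-specific exchange-weighting
function h(k). `ddex` is a research toolbox for people who need to know
which reading applies: it implements both frameworks, the theory that links
them, and the unified tMGE representation that uses DDE at several mixing
times to separate exchange from exchange-independent *transient* kurtosis
K<sub>ε</sub>.

The core quantities, for powder-averaged signals with total b-value b,
b-tensor shape b<sub>Δ</sub>² and kurtosis sensitivity b<sub>μ</sub>²:

* CTI: ln E = −b D̄ + ⅙ b² D̄² (K_I + b_Δ² K_A + b_μ² K_μ)
* 1D-MGE: ln E = −b D̄ + ⅙ b² D̄² K_T h(k), with
  h(k) = 2∫ q̃₄(t) e^(−kt) dt built from the fourth-order autocorrelation
  of the dephasing q-vector
* MGE/tMGE: ln E = −bD + ⅙ b² D² h(k)[K_I⁰ + h_Δ²(k) K_A⁰]
  + ⅙ b² D² [K_I^∞ + b_Δ² K_A^∞ + b_ε² K_ε]
* the bridge: K_μ = 2 K_T [h_SDE(k,Δ) − h_DDE(k,Δ,t_m)] — exchange
  masquerades as microscopic kurtosis

Everything is validated end-to-end against internal ground truth: an exact
Kärger matrix-exponential oracle for exchanging Gaussian pools, and a
compiled Monte Carlo random-walk engine for permeable restricted geometries
(packed spheres, cylinders, beads) with analytic confinement oracles.

## Worked example

CTI fitted to noiseless signals from two non-exchanging Gaussian pools
(D = 2 and 0.5 µm²/ms, equal fractions) on the 270-acquisition preclinical
protocol must find zero microscopic kurtosis:

```r
library(ddex)
library(dplyr)

proto   <- build_protocol(1)                  # sets of 45/45/135/45
signals <- proto |> mutate(signal = 0.5 * exp(-b * 2) + 0.5 * exp(-b * 0.5))
fit     <- fit_model(powder_average(signals), "cti", seed = 1)
tidy(fit)
#> # A tibble: 4 × 2
#>   term   estimate
#>   <chr>     <dbl>
#> 1 D       1.14
#> 2 K_I     0.688
#> 3 K_A     0
#> 4 K_mu   -0.00000000360
```

D̄ = 1.14 µm²/ms and K_I = 0.69 are the mean diffusivity and isotropic
kurtosis of the mixture seen through the second-order cumulant at these
b-values; K_A and K_μ are zero to numerical precision, as they must be for
isotropic Gaussian compartments without exchange.

With exchange switched on, the same CTI analysis reads the exchange as
microscopic kurtosis, while the MGE family estimates the rate itself:

```r
sub <- gaussian_substrate(
  list(gaussian_pool(2, fraction = 0.5), gaussian_pool(0.5, fraction = 0.5)),
  k = 0.05  # 50 1/s
)
p3  <- build_protocol(3, n_dirs = 6, narrow_pulse = TRUE)  # 11 mixing times
pt  <- powder_average(karger_signals(sub, p3))
fit <- fit_model(pt[pt$b <= 1, ], "mge1d", seed = 1)
tidy(fit)
#> # A tibble: 4 × 2
#>   term    estimate
#>   <chr>      <dbl>
#> 1 D         1.25
#> 2 K_T       1.00
#> 3 k         0.0481
#> 4 k_per_s  48.1
```

i.e. the exchange rate is recovered at 48 1/s (true 50 1/s; the few-percent
low bias from the truncated cumulant expansion is expected of the method),
with the mean diffusivity 1.25 µm²/ms exact and the total kurtosis slightly
below its ground truth of 1.08 for the same reason.

The main entry points are `build_protocol()` (the four acquisition designs),
`make_dde_waveform()`/`b_tensor()`, `h_sde()`/`h_dde()`/`h_numeric()` and
`H_tensor()`/`project_h()` (exchange weighting), `cti_signal()` /
`mge1d_signal()` / `mge_signal()` / `tmge_signal()` (forward models),
`karger_signal()`, `simulate_gaussian_exchange()`, `simulate_restricted()`
(ground truth), `powder_average()`, `add_rician_noise()`, `fit_model()`
(with broom-style `tidy()`/`glance()` and `autoplot()`),
`design_sensitivity()`, `recovery_study()` and `run_experiment()`.
A thin command-line wrapper lives at `inst/scripts/ddex.R`
(`simulate` / `fit` / `reproduce` subcommands).

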