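---
title: "Water exchange and transient kurtosis with double diffusion encoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Water exchange and transient kurtosis with double diffusion encoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddex)
library(dplyr)
```

## The problem

Double diffusion encoding (DDE) applies two pairs of diffusion-sensitising
gradient pulses separated by a mixing time $t_m$. Two analysis frameworks
read the same signal contrast — single diffusion encoding (SDE) versus
parallel DDE at equal total b-value — in two different ways:

* **Correlation tensor imaging (CTI)** attributes it to *microscopic
  kurtosis* $K_\mu$, the non-Gaussian signature of individual compartments;
* **Multi-Gaussian exchange (MGE)** attributes it to *intercompartmental
  water exchange* at rate $k$, which homogenises diffusivities over time and
  erodes the observed kurtosis.

`ddex` implements both frameworks, the theory connecting them, and a unified
representation (tMGE) that uses DDE at *multiple mixing times* to separate
exchange from the exchange-independent "transient" kurtosis
$K_\varepsilon$ of individual compartments. A Kärger matrix-exponential
oracle and a compiled Monte Carlo random-walk simulator provide ground truth
for validating the whole chain without external data.

## Signal representations

All models act on powder-averaged (spherically averaged) log-signals, with
b-values in ms/µm², diffusivities in µm²/ms and rates internally in 1/ms
(1/s at all I/O surfaces). Writing $b_\Delta^2$ for the b-tensor shape
(1 for SDE/parallel DDE, 1/4 for orthogonal DDE at $b_1=b_2$) and
$b_\mu^2 = (b_1^2+b_2^2)/(b_1+b_2)^2$ for the microscopic-kurtosis
sensitivity:

* **CTI** (`cti_signal()`):
  $\ln E = -b\bar D + \tfrac16 b^2\bar D^2 (K_I + b_\Delta^2 K_A +
  b_\mu^2 K_\mu)$. Fitted at a single long mixing time.
* **1D-MGE** (`mge1d_signal()`):
  $\ln E = -b\bar D + \tfrac16 b^2\bar D^2 K_T\, h(k)$, where $h(k) =
  2\int \tilde q_4(t) e^{-kt} dt$ is the exchange-weighting function of the
  waveform, built from the fourth-order autocorrelation of the dephasing
  q-vector. Fitted on the $\theta = 0$ subset.
* **MGE** (`mge_signal()`) extends this to anisotropic media through the
  exchange-sensitised square of the b-tensor $\mathbb H(k)$ and its
  isotropic/anisotropic projections $h(k)$ and $h_\Delta^2(k)$, plus
  persistent (non-exchanging) kurtosis terms $K_I^\infty, K_A^\infty$.
* **tMGE** (`tmge_signal()`) adds the transient kurtosis
  $b_\varepsilon^2 K_\varepsilon$ to the persistent bracket. Exchange makes
  the signal depend on the mixing time; transient kurtosis (assumed to reach
  its long-time value already at the shortest $t_m$) does not — that is the
  lever that separates the two. At least two distinct mixing times are
  required, and the representation is degenerate at $k = 0$ (the exchanging
  and persistent terms merge) and at very fast exchange (the mixing-time
  dependence collapses).

The bridge between frameworks is
$K_\mu = 2 K_T [h_{SDE}(k,\Delta) - h_{DDE}(k,\Delta,t_m)]$
(`kmu_from_exchange()`): in an exchanging multi-Gaussian system CTI reads a
non-zero, mixing-time- and rate-dependent $K_\mu$ even though every
compartment is Gaussian. Its small-rate linearisation is
$K_\mu = K_T(\tfrac23\Delta + t_m)k$; the relative error of that
linearisation grows linearly in $k$ (approximately
$k(\Delta+t_m)^2 / [4(\Delta/3+t_m/2)]$, i.e. about 5% at
$k\Delta = k t_m \approx 0.04$ and about 12% at 0.1), so it is a small-$k$
statement only.

## Exchange weights: normalisation and numerics

`h_numeric()` evaluates $h(k)$ by quadrature of the q-vector
autocorrelation. Narrow-pulse waveforms store q(t) as an exact
piecewise-constant function and the correlation is evaluated analytically at
a knot-refined lag grid (the only error is the trapezoid rule applied to
$e^{-kt}$, below $10^{-5}$ at the default grid); finite-pulse waveforms are
sampled at cell midpoints with dt = 10 µs. Closed forms `h_sde()`/`h_dde()`
switch to series expansions for $k\,T < 0.5$ to avoid catastrophic
cancellation.

The tensor generalisation `H_tensor()` is stored in a 6×6 Voigt form with
$\sqrt2$ off-diagonal scaling. Its projections (`project_h()`) use
$\mathbb I_I = \tfrac19\,\delta\otimes\delta$ and
$\mathbb I_A = \tfrac13 \mathbb I_{sym} - \mathbb I_I$. These constants are
*pinned by invariants* rather than assumed: they are the unique bulk/shear
normalisation for which $h(0) = 1$ and $h_\Delta^2(0) = b_\Delta^2$ hold for
every rephased waveform, and the test suite verifies both identities on all
protocol waveforms. For orthogonal DDE, $h_\Delta^2(k)$ *rises* from
$b_\Delta^2 = 1/4$ towards 1 with increasing rate — the isotropic component
of $\mathbb H(k)$ converges towards the anisotropic one — so the product
$h\,h_\Delta^2$ is not monotone for orthogonal waveforms (it is for SDE and
parallel DDE); the tests encode exactly this behaviour.

## Acquisition protocols

`build_protocol()` reproduces the four study designs: (1) the preclinical
CTI protocol (sets of 45/45/135/45 acquisitions at b = 2.5 split across
SDE, parallel, orthogonal and low-b parallel DDE; δ = 3.5 ms,
Δ = t_m = 12 ms; 45 electrostatically repelled rotations; three equidistant
second-pair directions for the orthogonal set); (2) the parallel/antiparallel
pair used for the long-mixing-time check; (3) the variable-mixing-time
protocol (eleven $t_m$ from 1–300 ms, six b-values 0.25–2.5 ms/µm²); and
(4) a clinical-timing variant (δ/Δ/t_m = 15.8/31.8/32.3 ms, nine mixing
times). Mixing time is defined as the gap from the end of the last pulse of
block 1 to the start of block 2, so that narrow pulses sit at
$0, \Delta, \Delta+t_m, 2\Delta+t_m$. Pulses are rectangular with
instantaneous ramps; amplitudes are set analytically so each block's b-value
is exact. For protocol 3's orthogonal set we use one second-pair direction
per rotation (the study design is explicit about three only for
protocol 1).

## Ground-truth simulators

Two engines generate signals for entire protocols from one trajectory set:
every block timing contributes a scalar dephasing profile $u_j(t)$, walkers
accumulate the moments $M_j = \sum_t u_j \,\mathrm d\mathbf r$, and every
rotation/b-value is scored as $\phi = a_1\mathbf n_1\!\cdot\!M_{p_1} +
a_2\mathbf n_2\!\cdot\!M_{p_2}$; the signal is the real channel
$\langle\cos\phi\rangle$.

* `karger_signal()` is the exact matrix-exponential solution for exchanging
  Gaussian pools under narrow pulses (any number of pools; detailed balance
  enforced and exploited for a symmetric eigen-decomposition).
* `simulate_gaussian_exchange()` adds per-step pool switching to free
  Gaussian walkers; it must agree with the Kärger oracle, and the test suite
  holds it to within 3 Monte Carlo standard errors.
* `simulate_restricted()` walks particles through periodic permeable
  geometries — simple-cubic packed spheres (d = 6 µm, 50% packing, lattice
  constant ≈ 6.09 µm), hexagonally packed cylinders (d = 1 µm, 75%), and
  axially periodic bead chains — with elastic specular reflection and
  membrane transmission probability $p = \kappa\sqrt{\pi\,dt/D_0}$.
  Because 50% sphere packing leaves gaps comparable to the step length,
  the engine tracks the *compartment identity* of each intracellular walker
  and treats a same-state step that lands in a different compartment as a
  double wall crossing; without this, walkers tunnel through contact points
  and the confinement statistics are wrong. Correctness is pinned by exact
  oracles: the uniform-ball displacement variance ($2R^2/5$ per axis) and
  the long-time structure-factor signal $|\rho(q)|^2$.
* For isotropic substrates `simulate_restricted()` optionally
  Rao-Blackwellises the rotation average of collinear-pair shells
  (`powder = "spherical"`): the exact spherical mean
  $\sin(|W|)/|W|$ of the per-particle phase replaces the discrete rotation
  scheme. This is an exact identity for the isotropic powder measure; note
  that it does not reduce the variance of kurtosis *contrasts*, whose
  fluctuations are radial (fourth-order) rather than directional.
* The **bead** profile is not fully specified by the study description
  (only min/max diameters 1 and 6 µm and 40% packing); we use a radius
  profile sinusoidal in $r^2$ with a 10 µm axial period, which spends enough
  length near the maximal diameter to make 40% packing attainable on a
  square lattice.

Exchange rates of geometries are always *measured*, not assumed:
`label_correlation()` records compartment-label self-agreement,
`measure_exchange_rate()` fits its mono-exponential decay (returning the
summed two-pool rate that enters $h(k)$, and flagging multi-scale decays),
and `calibrate_permeability()` bisects κ to a target rate.

Default desk scale is $10^5$ particles at dt = 2 µs for geometries
(the full study conditions are $10^6$ and 0.5 µs; Monte Carlo errors scale
as $\sqrt{10}$ between the two) and dt = 50 µs for Gaussian pools, where
only the exchange process and pulse boundaries need resolving.

What the generators emulate — exchanging Gaussian pools, permeable regular
packings, Rician noise at a configurable SNR — is exactly the study's
in-silico world. What they do not emulate: structural disorder and its
power-law time dependence, surface relaxation, T1/T2 decay during the mixing
time, gradient imperfections, and tissue-scale orientation dispersion beyond
what the substrate tensors encode. Passing tests therefore validate the
method chain, not the biological fidelity of any particular parameter value.

## Fitting

`fit_model()` mirrors the study's estimation procedure: bounded
Levenberg–Marquardt least squares (via `minpack.lm::nls.lm`, the R analogue
of MATLAB's `lsqnonlin`) from 10 random starts drawn uniformly between the
bounds, keeping the lowest-residual convergent solution. Default bounds:
$D \in (0, 4]$ µm²/ms, all kurtosis terms in $[-3, 5]$, $k \in [0, 0.5]$
1/ms. Residuals are formed on linear signals by default (sane noise
weighting; a log-domain option exists). $S_0$ can be fitted as a nuisance
scale for noisy data and is fixed to 1 for noiseless simulations. Exchange
weights are re-evaluated inside the objective at the current $k$: narrow
pulse shells use the closed forms; finite-pulse shells use pre-computed
binned lag series of the isotropic and anisotropic autocorrelation
projections, integrated against $e^{-kt}$ at call time (bin width 0.1 ms,
keeping the weight error well below the fit tolerances). Fits are
deterministic given a seed and invariant to row order (the table is sorted
internally).

Two analysis choices deserve emphasis:

* **Validity regime for exchange-rate recovery.** The second-order cumulant
  representations are $O(b^2)$ truncations. On two-pool Kärger signals with
  $\bar D = 1.25$ µm²/ms, fitting the full b-range up to 2.5 ms/µm²
  ($b\bar D \approx 3$) leaves a 15–25% low bias in $\hat k$ from the
  neglected higher cumulants — the "slight bias" expected of the method.
  Quantitative rate-recovery checks therefore fit the $b \le 1$ ms/µm²
  shells, where the truncation is controlled and recovery is within a few
  percent. This is a statement about where the representation applies, not a
  tuning of the estimator.
* **Timescale separation in tMGE.** tMGE's premise is that the process
  behind $K_\varepsilon$ is much faster than the resolvable exchange. If the
  exchange-rate search space includes the fast process itself (e.g. a
  100 1/s fast-mixing pair), the globally best single-rate fit *is* the fast
  process — mathematically a lower residual, but the answer to a different
  question. The three-pool disentanglement analysis therefore bounds the
  fitted rate to the slow regime ($k \le 25$ 1/s, i.e. exchange times
  resolvable by the 1–300 ms mixing-time range), which encodes the
  timescale-separation assumption explicitly.

`design_sensitivity()` quantifies when tMGE is invertible: at $k = 0$ the
exchanging and persistent kurtosis columns are exactly collinear; at
intermediate rates (tens of 1/s) the design has full column rank; at very
fast rates the mixing-time dependence of $h$ collapses (sooner for the
longer clinical timings). `recovery_study()` propagates Rician noise through
generate–corrupt–fit loops and reports per-parameter bias and spread.

## Worked example

CTI on a non-exchanging two-pool Gaussian substrate must return zero
microscopic kurtosis:

```{r cti-null}
proto <- build_protocol(1, n_dirs = 12, seed = 0)
signals <- proto %>% mutate(signal = 0.5 * exp(-b * 2) + 0.5 * exp(-b * 0.5))
fit <- fit_model(powder_average(signals), "cti", seed = 1)
tidy(fit)
```

Exchange masquerading as microscopic kurtosis, and its theoretical curve:

```{r kmu-curve, fig.width = 6, fig.height = 3.5}
plot_kmu_theory(K_T = 1, Delta = 12)
```

The tMGE separation mechanism on the kurtosis ladder:

```{r ladder}
kurtosis_ladder(K_I0 = 1, K_Iinf = 0.3, K_eps = 0.5, k = 0.02,
                Delta = 12, tm_list = c(1, 12, 100))
```

## Problem sizes used in the validation suite

The packaged tests run the chain at reduced but meaningful scale: $10^5$
particles / dt = 2 µs for the sphere-substrate CTI and long-mixing-time
checks, $10^5$ Gaussian walkers for the oracle-equivalence checks, 50 noise
repetitions at SNR = 200 for the tMGE recovery study, and 6–45 rotations
depending on whether the substrate is isotropic. These are the package's
standing validation conditions; heavier runs only tighten the Monte Carlo
error.

## Known limitations

* The multi-rate, multi-system extension of the exchange theory is out of
  scope: one total exchange rate is assumed shared by all exchanging
  ensembles.
* tMGE is restricted to DDE with fixed pulse duration and spacing per block
  (variable mixing times only), since $b_\varepsilon^2$ is defined from the
  block b-values.
* The narrow-pulse closed forms are used for fitting protocols realised
  with impulse gradients; finite-pulse fits go through the numeric weight
  path, which is validated against the closed forms in the δ → 0 limit.
* Monte Carlo walkers use a fixed step; reflection is specular with a
  bisection-located wall hit, and rare unresolvable corner steps are
  rejected. Discretisation bias is controlled by the structure-factor and
  confinement oracles at the packaged dt.
* At 50% sphere packing the extracellular gaps are ~0.1 µm; extracellular
  statistics very close to contact points are resolved only to the step
  length.
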