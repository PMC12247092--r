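# ihridme

Forward modelling and inversion of **intermolecular hyperfine RIDME**
(ih-RIDME) pulse EPR data.

ih-RIDME probes the nuclear (typically proton) environment of an unpaired
electron spin: during the longitudinal mixing block of a RIDME sequence,
nuclear flip-flops drive *hyperfine spectral diffusion* of the electron
resonance offset, and the resulting echo decay encodes the width σ of the
local hyperfine spectrum. For a nuclear configuration with spin quantum
number I and secular point-dipole couplings A<sub>j</sub>,

> σ² = I(I+1)/3 · Σ<sub>j</sub> A<sub>j</sub>²,

and σ is proportional to the local proton density (0.0215 MHz per mol L⁻¹
in water–glycerol glass). Heterogeneous samples — flexible spin-labelled
macromolecules, condensates, mixed phases — exhibit a *distribution* p(σ),
and the measured multi-mixing-time decay set

> V(t; T<sub>mix</sub>) = ∫ K(σt; T<sub>mix</sub>) p(σ) dσ · F(t)

can be inverted for p(σ) by a global non-negative fit of the
reference-divided traces. The package is written for EPR spectroscopists
and structural-biology modellers who want to simulate, fit and interpret
such data.

It provides:

* the spectral-diffusion kernel R(t; T<sub>mix</sub>) as an exact PDE
  (Crank–Nicolson) solution and as the closed form
  exp(−α(T<sub>mix</sub>)σ²t²), α = 1 − exp(−0.245 κT<sub>mix</sub>),
  κ = D/σ³ (`ridme_kernel()`, `evolve_spectrum()`);
* trace-set preprocessing (zero-time normalization with an echo-crossing
  exclusion window, reference division with a truncation floor) and the
  global model-free inversion with optional second-derivative (Tikhonov)
  regularization — `ridme_fit()`, a classed model object with
  `print`/`summary`/`coef`/`predict`/`plot`/`residuals`/`simulate`
  methods — plus relaxed (κ, β) scans (`scan_kernel_params()`);
* structure-based prediction of σ and p(σ) from coordinates: point-dipole
  couplings, the analytic shell formula (B ≈ 0.222 angular MHz nm³ for
  protons), powder averaging on a Fibonacci sphere grid, the anisotropic
  proton-cloud model, ensemble predictions with a spin-diffusion cutoff
  radius and cutoff scanning (`sigma_config()`, `sigma_shell()`,
  `cloud_model()`, `ensemble_sigma()`, `cutoff_scan()`);
* an exact density-matrix simulator for small electron–nuclear spin
  systems used as a validation oracle (`spin_system()`,
  `simulate_ridme()`, `hyperfine_states()`);
* a synthetic trace-set and toy-ensemble generator for numerical
  experiments (`simulate_traceset()`, `toy_ensemble()`), and a thin
  command-line interface (`exec/ihridme`, subcommands
  `simulate | fit | scan | predict | oracle`).

Units: times in µs, angular frequencies in 10⁶ rad s⁻¹ ("angular MHz"),
distances in nm.

## Worked example

Simulate a heterogeneous sample with a Gaussian density distribution
(centre 0.5 MHz, sd 0.18 MHz), five mixing times (30–480 µs, reference
30 µs) at SNR 50, and invert it:

```r
library(ihridme)

kp  <- kernel_params(kappa = 0.016, beta = 0.13)
ts  <- simulate_traceset(sigma = dist_gaussian(0.5, 0.18), snr = 50, seed = 1)
fit <- ridme_fit(normalize_traces(ts), kp)
summary(fit)
#> ih-RIDME global fit (reference-divided traces, approx kernel)
#>   kappa = 0.016 /us, beta = 0.13, lambda = 0
#>   p(sigma): mean 0.5033, sd 0.1992, skewness 0.302 (angular MHz)
#>   RMSD 3.686e-02 after 3000 iterations (not converged)
#>   per-trace residual RMS:
#>  Tmix=60 Tmix=120 Tmix=240 Tmix=480
#>  0.04010  0.03694  0.03595  0.03419
```

The fitted mean (0.503 MHz) and width (0.199 MHz) recover the generating
distribution (0.5, 0.18 MHz); the residual RMS per divided trace (~0.037)
reflects the roughly doubled noise of reference-divided data at SNR 50.
`sigma_concentration(0.5033, "sigma", "molar")` converts the mean to a
local proton concentration (23.4 M). The "not converged" flag only states
that the iteration cap was reached before the relative-improvement
criterion; on noisy data the remaining drift is far below the noise.

Structure side: a spherical proton cloud of radius 1.5 nm at 20 M placed
6 nm from the electron contains 170 protons, and its orientation-averaged
p(σ) resembles half a Pake pattern:

```r
cm <- cloud_model(d = 6, R = 1.5, CH = 20, seed = 1)
cm$n_protons
#> [1] 170
```

## Layout

* `R/` — kernel and signal model (`kernel.R`), distributions
  (`distribution.R`), trace sets (`traceset.R`), inversion (`fit.R`),
  structure module (`nucgeom.R`), density-matrix oracle
  (`spinoracle.R`), synthetic data (`synthdata.R`), I/O (`io.R`),
  constants (`constants.R`)
* `vignettes/ih-ridme-model.Rmd` — the model, its assumptions, numerical
  choices and limitations
* `tests/testthat/` — unit, property and end-to-end scientific tests
* `scripts/acceptance.R`, `exec/ihridme` — reproduction script and CLI
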