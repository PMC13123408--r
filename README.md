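# predope

Paramagnetic-doping analysis for ¹⁹F (and ¹³C) magic-angle-spinning NMR
relaxation studies of fluorine-labelled proteins.

## The problem

Biomolecular ¹⁹F MAS NMR is often sensitivity-limited by slow longitudinal
relaxation: with ¹⁹F T₁ of several seconds, most of the experiment is spent
waiting for polarisation to recover, because the recycle delay that maximizes
signal-to-noise per unit time is τ_opt = 1.26·T₁. Doping the sample buffer
with a paramagnetic agent — typically a Gd³⁺ chelate such as Gd(DTPA-BMA) or
Gd(DTPA) — shortens T₁ and thus the recycle delay, but too strong a dose also
shortens T₂ and broadens the lines until individual residue peaks merge. The
analysis task is to quantify both effects from titration data and find the
compromise.

`predope` implements that analysis chain for researchers running (or
planning) doping titrations on fluorotryptophan-labelled proteins:

* **Forward model** (`pre_gamma1`, `pre_gamma2`): the Solomon–Bloembergen
  dipolar PRE rates for an electron spin S at distance r from the nucleus,

  Γ₁ = (2/15)(μ₀/4π)² γ_I² g_e² μ_B² S(S+1) r⁻⁶ · [3J(ω_I) + 7J(ω_e)]

  Γ₂ = (1/15)(μ₀/4π)² γ_I² g_e² μ_B² S(S+1) r⁻⁶ · [4τ_c + 3J(ω_I) + 13J(ω_e)]

  with J(ω) = τ_c/(1 + ω²τ_c²). Γ₂ ≥ Γ₁ always, and both scale with the
  squared gyromagnetic ratio of the nucleus — which is why ¹³C PREs are ~14×
  weaker than ¹⁹F PREs at the same dopant concentration.
* **Spectrum engine** (`simulate_spectrum`, `fit_peaks`,
  `extract_intensity_series`): 1D spectra as sums of Lorentzians
  (fwhm = R₂/π), peak fitting with locked positions/widths across the slices
  of a pseudo-2D relaxation series, noise estimation, and a resolvability
  flag that detects when broadening merges neighbouring peaks.
* **Relaxation fitting** (`fit_saturation_recovery`, `fit_decay`,
  `monte_carlo_errors`): mono-exponential fits M∞(1−e^(−τR₁)) and
  M₀e^(−τR₂) with parametric Monte Carlo error propagation (500 iterations
  by default) using the spectral noise standard deviation.
* **Titration analysis** (`bulk_rate`, `fit_pre`, `pre_pattern`): bulk rates
  as unweighted averages over residues (averaging rates, not time
  constants), and PREs Γ₁/Γ₂ as ordinary least-squares slopes of R₁/R₂
  versus dopant concentration, with Monte Carlo slope errors.
* **Sensitivity** (`optimal_recycle_delay`, `time_gain`,
  `sensitivity_report`): the 1.26·T₁ rule, its derivation as the maximizer
  of (1−e^(−x))/√x, and the recycle-delay/measurement-time fold-change a
  doping level buys.
* **Structure descriptors** (`d_rss`, `sasa`, `structure_descriptors`):
  root-sum-square dipolar coupling between each tryptophan's 5-position
  (CZ3, the fluorination site) and all back-exchangeable protons of the
  assembly, and Shrake–Rupley solvent-accessible surface area — descriptors
  for rationalising why per-residue PREs differ.
* **Synthetic study** (`default_design`, `generate_study`, `end_to_end`): a
  complete in-silico titration with known ground truth, so the whole chain
  is testable without measured data.

## Worked example

```r
library(predope)

# forward model: Gd3+ (S = 7/2), tau_c = 100 ps, 19F at 14.09 T
sys <- paramagnetic_system(S = 7/2, tau_c = 100e-12, nucleus = "19F", B0 = 14.09)
pre_predict(sys, c(5, 10, 15))
#>   r_A  gamma1_s1 gamma2_s1
#> 1   5 7830.85285 9793.0956
#> 2  10  122.35708  153.0171
#> 3  15   10.74191   13.4336
```

The r⁻⁶ law is steep: moving the electron from 5 to 15 Å cuts the PRE by
nearly three orders of magnitude.

```r
# fit a noisy saturation-recovery series (true T1 = 6 s, 2 % noise)
delays <- exp(seq(log(0.01), log(20), length.out = 12))
ser <- simulate_relaxation_series(6.0, delays, noise_frac = 0.02,
                                  experiment = "satrec_T1",
                                  label = "W136", seed = 1)
fit <- monte_carlo_errors(fit_saturation_recovery(ser), n_iter = 500, seed = 1)
fit
#> <rate_fit W136 satrec_T1> converged
#>   R = 0.1696 s^-1  T = 5.895 s  amplitude = 1.011
#>   rate_err = 0.0102 s^-1 (MC, n=500)
optimal_recycle_delay(fit$time_constant)
#> [1] 7.43
```

The fitted T₁ of 5.9 s implies a 7.4 s optimal recycle delay — doping exists
to shrink exactly this number.

```r
# the full in-silico titration: generate -> fit -> slopes -> sensitivity
rep <- end_to_end(default_design(), seed = 1, n_mc = 50)
rep
#> <study_report>
#>   66 rate fits, 20 PRE fits
#>   bulk Gd(DTPA-BMA) R1: Gamma = 0.1009 +/- 0.0024 (true 0.101) s^-1 mM^-1
#>   bulk Gd(DTPA-BMA) R2: Gamma = 37.98 +/- 1.3 (true 38.2) s^-1 mM^-1
#>   bulk Gd(DTPA) R1: Gamma = 0.7397 +/- 0.044 (true 0.743) s^-1 mM^-1
#>   bulk Gd(DTPA) R2: Gamma = 549.2 +/- 19 (true 556.2) s^-1 mM^-1
#>   bulk T1 2.6 -> 0.842 s; tau_opt 3.28 -> 1.06 s (fold 3.09)
```

Every slope is recovered within its Monte Carlo error; the mild dopant at
8 mM shortens the recycle delay about 3-fold while the per-residue peaks stay
resolved, whereas the strong dopant at 8 mM merges them (the pipeline then
falls back to a single bulk envelope, flagged `resolution_lost`).

A thin command-line wrapper is installed at `inst/cli/predope` with
subcommands `sbm`, `sensitivity`, `simulate`, `end-to-end`,
`fit-relaxation`, `fit-pre` and `descriptors`; every subcommand is a direct
call into the functions above.

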