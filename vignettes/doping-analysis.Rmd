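---
title: "Paramagnetic doping analysis: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paramagnetic doping analysis: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(predope)
```

## Scope

`predope` models and analyses doping titrations for ¹⁹F MAS NMR of
fluorotryptophan-labelled proteins: a paramagnetic co-solute (a Gd³⁺
chelate) is added at increasing concentration, per-residue longitudinal and
transverse relaxation rates are measured from pseudo-2D relaxation
experiments, and the paramagnetic relaxation enhancements (PREs) Γ₁ and Γ₂
are extracted as the slopes of R₁ and R₂ versus concentration. The package
covers the forward physics, the spectral and relaxation fitting, the
titration statistics, the recycle-delay economics, and two structural
descriptors used to rationalise per-residue differences.

## The forward model and its assumptions

The PRE of a nucleus at distance $r$ from an unpaired electron system with
spin quantum number $S$ is taken as the dipolar Solomon–Bloembergen form

$$\Gamma_1 = \frac{2}{15}\Big(\frac{\mu_0}{4\pi}\Big)^2
\gamma_I^2 g_e^2 \mu_B^2 \frac{S(S+1)}{r^6}
\left[\frac{3\tau_c}{1+\omega_I^2\tau_c^2}
 + \frac{7\tau_c}{1+\omega_e^2\tau_c^2}\right],$$

$$\Gamma_2 = \frac{1}{15}\Big(\frac{\mu_0}{4\pi}\Big)^2
\gamma_I^2 g_e^2 \mu_B^2 \frac{S(S+1)}{r^6}
\left[4\tau_c + \frac{3\tau_c}{1+\omega_I^2\tau_c^2}
 + \frac{13\tau_c}{1+\omega_e^2\tau_c^2}\right].$$

Assumptions: a point-dipole electron, isotropic rotational modulation with
a single correlation time $\tau_c$, and no Curie-spin, contact or
cross-correlated contributions (reasonable for small, fast-tumbling Gd³⁺
chelates in the buffer). Inner-sphere water exchange — one reason different
chelates with the same $S$ produce very different effective PREs — is not
modelled; the package treats measured Γ values as empirical slopes and the
forward model as an interpretive tool. The spectral-density term
$J(\omega) = \tau_c/(1+\omega^2\tau_c^2)$ is bounded by $\tau_c$, from which
$\Gamma_2 \ge \Gamma_1$ follows algebraically for all parameters; the
electron Larmor frequency is derived as
$\omega_e = g_e \mu_B B_0/\hbar$ (the standard relation; it is part of this
package's definition of the model rather than something the expressions
above make explicit).

Key parameters, units and defaults:

| parameter | meaning | default | why |
|---|---|---|---|
| `S` | electron spin | 7/2 | Gd³⁺ |
| `ge` | electron g value | 2.00232 | free-electron value, appropriate for Gd³⁺ |
| `tau_c` | correlation time (s) | 100 ps | plausible order of magnitude for a small chelate; **override for quantitative work** — it is not a measured quantity here |
| `B0` | static field (T) | 14.09 | 600 MHz ¹H instrument class |
| `nucleus` | observed spin | ¹⁹F | the labelling scheme's probe |
| `r` | electron–nucleus distance (Å) | user input | the quantity of interest |

Constants are CODATA values; γ(¹⁹F)/γ(¹H) ≈ 0.941, so ¹⁹F enjoys nearly
proton-strength PREs, while γ(¹³C)/γ(¹⁹F) squared ≈ 0.071 explains the much
weaker ¹³C enhancements.

## Spectra and intensity extraction

Peaks are pure Lorentzians in height-normalized form; this is the physical
lineshape for exponential decay and keeps the link fwhm = R₂/π exact, which
the resolution analysis relies on. Intensity is the fitted peak *height*,
not the integral: with positions and widths locked, height is proportional
to the underlying magnetisation and is what a peak fitter reports stably on
low-signal slices.

For a pseudo-2D series the reference slice (largest total signal) is fitted
freely; all other slices are refit with positions and widths locked, so the
amplitude estimation becomes an exact linear least-squares solve. Locking
stabilises the weakest slices (early recovery delays, late echo delays)
and makes the per-peak intensity series well defined. A peak is flagged
unresolvable when its fitted width exceeds the distance to its nearest
neighbour; at that point per-residue analysis stops and the merged envelope
is treated as a single bulk peak.

Noise is estimated as the standard deviation of a signal-free spectral
region (at least 32 points) and pooled across slices (root mean square).
With broad peaks the Lorentzian tails bleed slightly into any finite
region, so the estimate is conservative by a few percent at the strongest
doping levels; this inflates Monte Carlo errors marginally and is accepted.

## Relaxation fitting and error propagation

Saturation recovery is fitted as $M(\tau) = M_\infty(1-e^{-\tau R_1})$ with
*no offset*: the presaturation train in the underlying experiment (50
repetitions) justifies assuming complete saturation at $\tau = 0$. A
three-parameter variant with offset exists behind `offset = TRUE`. Echo
decays are fitted as $M(\tau) = M_0 e^{-\tau R_2}$. Fits use
Levenberg–Marquardt with analytic-free starting values obtained from a
log-linearisation; failures (non-convergence, non-positive rate, all-zero
input) are flagged with a message, never silent.

Uncertainties come from parametric Monte Carlo: synthetic series are drawn
as best-fit curve plus Gaussian noise at the estimated spectral σ, refit,
and the standard deviation of the refitted rates is the reported error
(default 500 iterations; a residual bootstrap is deliberately not used —
the noise model is known and parametric resampling matches it). If more
than 10 % of refits fail the result is flagged. Calibration is tested:
across the T₁ range 0.5–8 s at 2 % noise, roughly 68 % of true rates fall
within one reported error.

## Titration statistics

Bulk rates average *rates*, not time constants: the bulk time constant is
$1/\overline{R}$, and $\overline{T} \ne 1/\overline{R}$ — with per-residue
T₁ of 1.67/2.6/2.5/6.0 s the two conventions give 2.58 s versus 3.19 s.
The package reports the rate-average convention prominently because slopes
of rates are the quantity that is linear in dopant concentration.

PRE slopes use unweighted ordinary least squares with a free intercept (the
diamagnetic rate). Weighted OLS (1/σ²) is available behind a flag but not
default, since per-residue error estimates are themselves noisy for small
delay grids. Slope errors are reported twice: analytic OLS errors and
Monte Carlo errors from resampling the input rates within their one-sigma
uncertainties (500 seeded iterations); the MC value is the primary one, for
consistency with the rate-level error philosophy. Negative fitted slopes
are allowed but flagged. Two-point fits (the strong-dopant per-residue
case) have no residual degrees of freedom, so only the MC error is
meaningful there.

A residue missing at some concentration (lost to broadening) is simply
omitted from that residue's fit; the bulk fit uses all concentrations where
any bulk measurement exists, taking the merged-envelope rate where
per-residue peaks are gone. On complete data the bulk slope equals the mean
of per-residue slopes exactly (linearity of OLS); with unequal coverage the
two diverge, and the package surfaces both rather than hiding the
difference.

## Recycle-delay economics

For a saturation-recovery-type experiment the per-transient signal is
$1-e^{-\tau/T_1}$ and the SNR per unit measurement time is
$f(\tau/T_1)/\sqrt{T_1}$ with $f(x) = (1-e^{-x})/\sqrt{x}$. The maximizer
of $f$ is 1.2564…, conventionally rounded to 1.26, giving
$\tau_{opt} = 1.26\,T_1$; `optimal_factor()` computes the exact maximizer
numerically so the convention is auditable. Because $f(x_{opt})$ is
independent of $T_1$, the equal-SNR measurement-time ratio between two
samples is simply the ratio of their T₁ values — this is the "fold change"
a doping level buys. Flip-angle (Ernst-angle) optimisation is out of scope:
direct 90°-pulse excitation is assumed.

## Structure descriptors

Two per-tryptophan descriptors are computed from a PDB model:

* **d_rss**, the root-sum-square dipolar coupling between the fluorine site
  and all back-exchangeable protons, a proxy for the ¹H dipolar network that
  distributes the PRE through spin diffusion. The fluorine is placed at the
  CZ3 position itself (the 5-position carbon that carries the fluorine in
  the labelling scheme); the ~1.3 Å C–F bond offset is well within the
  interpretive precision of the descriptor. "Back-exchangeable" is
  interpreted as backbone amide H plus side-chain N/O/S-bound hydrogens,
  the set that re-protonates when a perdeuterated protein is exchanged into
  H₂O buffer. For hydrogen-less crystal structures, amide protons are built
  geometrically (1.01 Å from N along the negated bisector of the N–CA and
  N–C(i−1) directions, i.e. trans to the preceding carbonyl) and
  side-chain exchangeables are placed 1.0 Å from their heavy atom pointing
  away from its bonded neighbours, weighted by the site's standard proton
  count. The default context is the full assembly (all chains), since
  inter-subunit protons are genuine coupling partners in an oligomer; a
  monomer mode exists behind a flag.
* **SASA** by the Shrake–Rupley rolling-probe construction: probe 1.4 Å,
  960 deterministic quasi-uniform sphere points per atom (golden-spiral
  layout, so results carry no seed), van-der-Waals radii H 1.2, C 1.7,
  N 1.55, O 1.52, S 1.8 Å. The algorithm is implemented in the package and
  verified against the analytic sphere (≤1 %) and the exact two-sphere
  spherical-cap formula (≤2 %).

Descriptor–PRE association uses Pearson correlation with an exact
permutation p-value (all n! label permutations enumerated; with four
residues the null has only 24 points, so the smallest attainable p is
1/12 two-sided — a deliberate reminder of how little such a correlation can
prove at n = 4).

## The synthetic study

`default_design()` encodes the study conditions the package is built
around: residues W106/W136/W164/W276 with diamagnetic ¹⁹F T₁ of
2.6/6.0/1.67/2.5 s; Gd(DTPA-BMA) at 0/2/4/6/8/16 mM with bulk
Γ₁ = 0.101 and Γ₂ = 38.2 s⁻¹mM⁻¹; Gd(DTPA) at 0/2/8 mM with bulk
Γ₁ = 0.743 and Γ₂ = 556.2 s⁻¹mM⁻¹ and per-residue coverage only at
0/2 mM. Per-residue slopes are seeded perturbations of up to ±30 % around
the bulk, constrained to average exactly to the bulk; they are invented
spreads, as are the diamagnetic T₂ values (4–5.5 ms), the four ¹⁹F shifts
(−122.3/−123.4/−124.6/−125.9 ppm) and the peak amplitudes — all flagged in
`design$synthetic_defaults`. Delay grids are 12 log-spaced points over
0.01–20 s (T₁) and 10 over 0.1–50 ms (T₂), chosen to bracket every time
constant in the design. Noise is additive i.i.d. Gaussian per spectrum
point at 2 % of the maximum clean signal, all derived deterministically
from one root seed.

Note one arithmetic consequence of the averaging convention: the
rate-average bulk T₁ of the default design is 2.58 s (not the
time-constant average 3.19 s), so end-to-end reports show a diamagnetic
bulk T₁ near 2.6 s.

The generator reproduces the qualitative resolution behaviour: at 8 mM of
the strong dopant the predicted broadening (≈1.4 kHz) exceeds the smallest
peak separation (≈620 Hz) and the generator emits a merged envelope marked
`resolution_lost`, while 8 mM of the mild dopant (≈190 Hz linewidth) leaves
all four peaks resolvable.

What the generator does **not** emulate: static and MAS-related lineshape
structure (sidebands, CSA), cross-polarisation transfer efficiency for
¹³C-detected variants (absorbed into amplitudes), baseline and phase
artefacts, temperature drift, binding of the dopant to the protein (PREs
are strictly linear in concentration by construction), and spin-diffusion
dynamics. Passing closed-loop tests therefore demonstrates that the
analysis chain is self-consistent and unbiased under its own noise model —
not that real spectra meet these idealisations.

## Problem sizes and numerical choices

The test-suite and acceptance runs use deliberately compact problem sizes:
100 seeded series per parameter-recovery check, 80–200 series for
calibration properties, Monte Carlo depths of 25–60 inside pipeline tests
(the user-facing default stays 500), and four generation seeds for the
closed-loop identifiability property. These sizes give comfortable
statistical margins for each assertion while keeping a full run fast on a
single CPU. Nonlinear fits use `minpack.lm`'s Levenberg–Marquardt with
log-linearised starting values; ties and degenerate inputs (all-zero
series, two-point titrations, exact collinearity) are handled explicitly
and tested. The 17-significant-digit text format of the P2D-CSV interchange
makes write/read round trips bit-exact.

## Known limitations

* τ_c and S enter predictions only; no attempt is made to fit them from
  measured Γ values (the inverse problem is under-determined with two
  observables per condition).
* The merged-envelope bulk rate at resolution loss is a single-Lorentzian
  fit to a multi-component line; it is a pragmatic summary, not a
  physically exact bulk average, and is flagged as such in outputs.
* Exchangeable-proton construction for hydrogen-less structures is
  idealised geometry; for quantitative d_rss work a properly protonated
  model is preferable.
* The permutation test at n = 4 has a granular null; it can flag perfect
  (anti)correlations only at p = 1/12.
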