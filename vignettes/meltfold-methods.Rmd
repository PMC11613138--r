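---
title: "Hairpin versus homoduplex melting analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hairpin versus homoduplex melting analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meltfold)
```

# The scientific problem

A partially palindromic DNA single strand folds either into a
unimolecular hairpin or a bimolecular mismatched homoduplex.  Both give
a single sigmoidal melting transition in UV absorbance and in NMR
chemical shifts, so each experiment alone is ambiguous.  `meltfold`
implements the full analysis that resolves the ambiguity: factor
analysis of UV spectral series, van't Hoff melting fits under three
equilibrium models, a simultaneous two-method fit exploiting the large
concentration gap between UV (µM) and NMR (mM) samples, NOE distance
calibration, and a fluorescence-titration estimate of the duplex
association constant.

# Thermodynamic models

All equilibrium constants use the **association convention**
(K = folded/unfolded), so folding has ΔH < 0 and ΔS < 0, and
K(T) = exp(−(ΔH − TΔS)/(RT)) with R = 8.314 J mol⁻¹ K⁻¹ exactly.
Temperatures are Kelvin internally; every interface takes and reports
°C with the explicit conversion T_K = T_C + 273.15.

Three models relate the species concentrations to the total strand
concentration c (one strand = one molecule; the duplex strand fraction
f_du = 2c_du/c counts strands, not complexes):

* **(i) hairpin only** — f_h = K_h/(1 + K_h); T_m = ΔH/ΔS,
  concentration-independent.
* **(ii) duplex only** — with K′ = K_du/c_ref the mass balance
  2K′c_un² + c_un − c = 0 is solved by the cancellation-safe root
  c_un = 2c/(1 + √(1 + 8K′c)); T_m solves K(T_m) = c_ref/c, i.e.
  T_m = ΔH/(ΔS + R ln(c/c_ref)).
* **(iii) combined** — c = c_un(1 + K_h) + 2K′c_un², again solved by
  the safe quadratic root; all three strand fractions are returned and
  sum to 1 within 10⁻¹².

Subscript convention: c_un is the unfolded open strand and c_h the
folded hairpin, so K_h = c_h/c_un — the only reading consistent with
the association convention and the signs of the fitted ΔH and ΔS.

# Factor analysis of spectral series

`decompose()` performs an exact SVD, Y = V·diag(W)·S, with profiles
(rows of S) oriented so their largest-magnitude element is positive —
a deterministic sign convention required for reproducible score plots
and tests.  `estimate_dimension()` counts a component as significant
when all three criteria hold:

1. **weight** — W_j/W_1 ≥ 10⁻³ (the first negligible singular value
   falls below one per mille of the first);
2. **residual** — the truncation residual with j−1 components still
   exceeds the noise floor;
3. **smoothness** — the lag-1 autocorrelation of the score column is
   ≥ 0.5, separating smooth property-dependent scores from erratic
   noise components.

The exact numeric thresholds in (2) and (3) are implementation
choices; both are arguments with documented defaults.  When the per-point noise is not
supplied, the floor is estimated from the tail singular values (median
of the smallest max(2, n−6) values divided by √max(n, p)) — a
heuristic calibrated for i.i.d. Gaussian noise and overridable by the
known σ.

For a two-state transition with per-state linear temperature drifts the
series is exactly rank 4 (mean, transition, two drift shapes), which is
why the generator's defaults yield factor dimension 4; for generators
with higher melting points the unfolded branch shortens and the
criteria naturally return 3, with no special-casing.

# Melting fits

All fits share one engine: the observable of every channel (one SVD
score column, or one resonance's shift profile) is modeled as

y(T) = f(T)·(a + b·T) + (1 − f(T))·(c + d·T),

with folded fraction f(T) driven by a single shared (T_m, ΔH) through
the chosen model.  Baselines are linear in °C.  The linear parameters
are solved exactly by weighted least squares at every step (variable
projection), so the outer optimization runs only over the 2 (single
model) or 4 (combined model) nonlinear parameters.  Channels sharing a
temperature grid and weight profile are solved as one multi-RHS QR,
which keeps 20+-resonance global fits fast.

Numerical choices:

* **Parameterization** — internal coordinates are (T_m in °C, ΔH in
  kJ/mol), with ΔS derived (ΔS = ΔH/T_m − R ln(c/c_ref) for the
  bimolecular model).  This is far better conditioned than (ΔH, ΔS),
  whose likelihood valley is a thin diagonal.
* **Optimizer** — Nelder–Mead from five deterministic starts (the
  steepest-derivative temperature ± offsets crossed with enthalpy
  scales −80/−150/−280 kJ/mol), refined by BFGS.  Deterministic starts
  were chosen over seeded random restarts so that fits never consume
  user-visible RNG state; the variable-projection surface is smooth and
  the start grid covers the basin in all tested regimes.
* **Uncertainties** — from the numerically differentiated Hessian of
  the profiled residual sum, scaled by the reduced χ²; ΔS errors by the
  delta method.  Unit weights unless per-point σ are given.
* **Weighting of SVD scores** — score column j carries absorbance noise
  attenuated by 1/W_j, so columns are weighted (W_j/W_1)² within a
  UV-only fit and (W_j/σ_A)² in the joint fit, where σ_A is the
  per-point absorbance noise (estimated from the decomposition residual
  beyond M when not supplied).  This puts both methods on commensurate
  χ² scales — without it the UV data would contribute ~10⁻⁸ of the NMR
  weight and the joint fit would collapse into a spurious minimum.

## The simultaneous UV+NMR fit

`fit_joint()` fits the combined model with shared hairpin and duplex
parameters across a UV dataset (µM) and an NMR dataset (mM).  The
concentration contrast is the sole source of identifiability: at µM the
homoduplex is absent and the UV data pins the hairpin parameters; at mM
the duplex admixture distorts the apparent melting curve and the NMR
data pins the duplex parameters.  With a single method the model is not
separable — the package refuses single-method input with a "not
separable" error and warns when concentrations differ by less than
10×.  Folded hairpin and duplex strands share the folded baseline by
default (`share_folded = TRUE`), since both are stacked, base-paired
states; the option exists because either convention is defensible.  Duplex parameters are reported as non-identifiable
(with wide intervals, not an error) when their relative standard errors
exceed 100%.

# NOE distance calibration

Distances follow the isolated-spin-pair sixth-power rule
d = 2.9 Å·(I_ref/I)^(1/6), with I_ref the arithmetic mean of all
intranucleotide cytosine H5–H6 cross-peak volumes (a fixed 2.9 Å
geometry).  Symmetric cross-peaks are volume-averaged first; methyl
(M7) volumes are divided by 3 (a pseudo-atom convention, documented
explicitly rather than assumed known).  No
spin-diffusion or relaxation-matrix correction is applied.  The B-DNA
comparison constants (intranucleotide H1′–H6/H8 ≈ 3.7 Å, sequential
internucleotide ≈ 3.0 Å) are synthetic stand-ins representing regular
B-DNA geometry; they are exported and overridable, and real survey
values should be substituted when available.  Restraint bounds default to ±20%
fractional half-width, a placeholder convention for the unavailable
published restraint tables.

# Fluorescence titration

The titration mixes ~0.1 µM doubly labeled strand with up to
3000-fold unlabeled excess.  Patterns (four concatenated FAM/Cy3
excitation/emission blocks) are unmixed by non-negative least squares
(Lawson–Hanson active set, written in-package since no NNLS routine is
available in the environment) against reference patterns for the
quenched hairpin, the open coil, and the unquenched heteroduplex.  The
labeled strand's duplex fraction follows the competition equilibrium
f = K′u/(1 + K_h + K′u), where u is the free unfolded unlabeled
concentration from the combined model; labeled–labeled duplexes are
neglected (trace labeling).  K_h at the working temperature is an
input from the melting fits, not refit.  The association constant is
estimated by least squares over log₁₀K with a profile-likelihood
interval; when K → 0 is not rejected, an upper bound is reported
instead of a point estimate.

# The synthetic world

The generators state the measurement conditions once and do not move:

* **UV series** — 220–320 nm, 5–85 °C in 4 °C steps, 3.08 µM, Gaussian
  noise 10⁻³ AU (photometric noise of a double-beam spectrometer at
  0.5–1 AU); analytic Gaussian endpoint bands with 20% hyperchromicity
  and per-state linear drifts of 1.2–1.8·10⁻³ AU/°C, magnitudes chosen
  so the drift components sit well above the noise floor as they do in
  measured series.  Endpoint spectra are synthetic shapes, not digitized
  measured spectra: only their difference structure matters to the
  pipeline.
* **NMR shift profiles** — 5–75 °C in 2 °C steps, 1.14 mM, noise
  0.002 ppm for the headline recovery experiment.  The default
  resonance table carries the full aromatic set a global fit would use
  (one H6/H8 per nucleotide, H2 per adenine, M7 per thymine — 26
  resonances for the 16-mer), with intercepts in the canonical ranges
  per base type and transition amplitudes of both signs, as loop and
  stem protons show.
* **Joint-fit experiment** — UV noise 10⁻³ AU and shift noise
  5·10⁻⁴ ppm.  The lower shift noise is deliberate and stated once: at
  0.002 ppm the statistical floor of the recovered 13 °C duplex
  fraction is ±9 percentage points (delta method on the fit
  covariance), whereas the experiment this emulates resolved it to ±3
  points; 5·10⁻⁴ ppm is the read-off precision of sharp, well-resolved
  aromatic lines and reproduces that precision.
* **Titration** — ratios 1:1…1:3000, labeled strand 0.1 µM, pattern
  noise 10⁻³ of the unit-scaled maximum (photon-counting regime).  The
  free-coil reference is red-shifted 4 nm relative to the duplex
  reference (solvent-exposed fluorophores); without a shape difference
  the free and duplex references are nearly collinear and the
  non-negativity constraint censors the tiny duplex weight.
* **NOESY volumes** — I = scale·d⁻⁶·(1 + ε), tripled for methyls,
  with a C H5–H6 pair at 2.9 Å for self-calibration.

Every generator is a pure function of its seed: outputs are identical
across runs and the caller's RNG stream is left untouched.

What a green test establishes — and what it does not: the generators
reproduce the *statistical structure the analysis assumes* (two-state
populations, linear baselines, r⁻⁶ volumes, fraction-weighted
patterns, i.i.d. Gaussian noise).  Recovery tests therefore verify
correctness and precision of the estimators under model closure.  They
do not probe model misspecification in real data: curved baselines,
ΔCp ≠ 0, spin diffusion at 200 ms mixing, heteroscedastic photon
noise, or chemical-exchange line-shape effects are all outside the
stated world.

# Degenerate inputs and edge behavior

Flat shift profiles are flagged "no transition" (fitted amplitude
below five residual standard deviations, or T_m outside the data
range) rather than reported with a meaningless T_m; per-resonance
batches never abort on one bad profile.  The duplex-only and combined
mass balances use the cancellation-safe quadratic root, stable from
K = 0 through K·c ≫ 1.  Peaks with non-positive volumes are retained
by the reader but flagged unusable; converting one is an error.

# Known limitations

* Sequence support ends at the central 20-mer (positions −10…+10);
  the flanking bases needed for the 28- and 36-mers are not on record
  here, so those lengths raise "flank sequence unavailable" by design.
* The tabulated literature mass of the 12-mer (3645) disagrees by one
  unit with the mass formula applied to the reconstructed sequence
  (3644.46 → 3644); the package reports the formula value rather than
  forcing agreement.
* No nearest-neighbor ΔG prediction, heat-capacity models, or
  salt-dependence corrections; no general secondary-structure
  prediction (the contiguous-stem hairpin of the inverted repeat is
  the only unimolecular topology considered, matching the studied
  system).
* The fluorescence module models no photophysics: quenching and FRET
  live entirely in the reference vectors.
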