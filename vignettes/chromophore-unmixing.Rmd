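---
title: "Chromophore unmixing of tissue absorption spectra: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromophore unmixing of tissue absorption spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromounmix)
```

## The problem

Tissue discriminates itself spectrally: the broadband absorption
coefficient $\mu_a(\lambda)$ of a tissue carries the signatures of its
light-absorbing constituents — hemoglobin's Soret band near 415 nm and
Q-bands at 540/570 nm, DNA near 260 nm, proteins near 230 nm, water at
980 nm, and the wavelength-decreasing ultraviolet baseline of pigments such
as melanin and lipofuscin. Quantifying how much of each chromophore a
tissue contains, and how those amounts shift between healthy and cancerous
tissue, is diagnostic information. This package implements that analysis
for thin-slab integrating-sphere measurements: direct computation of
$\mu_a(\lambda)$, linear decomposition against a chromophore library, and
conversion of the fitted weights into volume concentrations.

## The slab absorption model

For a slab of thickness $d$, every photon is transmitted, reflected, or
absorbed, so

$$\mu_a(\lambda) = \frac{1 - \left(T_t(\lambda) + R_t(\lambda)\right)}{d}.$$

This is an energy-balance approximation, not a radiative-transfer
inversion: scattering path-length enhancement is folded into the effective
absorption, which is adequate for thin (0.5 mm) slabs and is what makes
the computation direct and instantaneous. Two numerical policies follow
from measurement reality:

* **Negative raw values.** Noise can push $T_t + R_t$ slightly above 1
  where true absorption is near zero. The raw value is clipped to 0 and
  the wavelength recorded in `clipped_points`; clipping rather than
  erroring keeps noisy but otherwise valid measurements usable, and the
  annotation keeps the event auditable.
* **No smoothing.** No despiking or smoothing is applied to $T_t$/$R_t$
  before the calculation; the ensemble mean across samples is the only
  averaging in the pipeline.

Units are the biophotonics convention: thickness in cm, $\mu_a$ in 1/cm
(user-facing interfaces take `thickness_mm` and convert; the 0.5 mm
default is `thickness_cm = 0.05`). Per-wavelength dispersion uses the
sample standard deviation (divisor $n-1$), appropriate for the small
cohorts (about 10 samples per condition) this analysis is designed around.

## The unmixing fit

The mean spectrum $y$ of a condition is modeled as $y = Xb$ where column
$i$ of $X$ is the library spectrum $\mu_{a,i}(\lambda)$ and
$b = (X^\top X)^{-1} X^\top y$ is the least-squares weight vector. Design
choices, where the method left room:

* **Solver.** Production uses a QR factorization, with the literal
  normal-equations inversion retained only as a test oracle: forming
  $X^\top X$ squares the condition number, and chromophore libraries are
  intrinsically overlapping in the UV. Rank-deficient designs return the
  minimum-norm (SVD pseudoinverse) solution with a warning rather than
  failing — duplicate or collinear user libraries should degrade loudly,
  not fatally.
* **Library scale.** Library spectra are 0–1 normalized before entering
  the design matrix. With heterogeneous literature sources the absolute
  scales of component spectra are not mutually consistent; a shared scale
  makes weights comparable across components, and the downstream
  proportional concentration rule is only unit-consistent under a common
  column scale. The convention is recorded in the run summary
  (`library_scale: normalized_0_1`) and configurable through the library
  manifest.
* **Fit target and domain.** The fit is to the ensemble mean (per-sample
  fitting is available by calling `solve_weights` on individual spectra),
  over the full 200–1000 nm grid, unweighted. The default grid is 1 nm
  sampling (801 points), a spectrometer-class resolution that keeps the
  normal equations well-posed.
* **Negative weights.** Plain least squares is the default; negative
  weights trigger a prominent warning pointing to the
  non-negativity-constrained variant (`nonneg = TRUE`, Lawson–Hanson via
  `pracma::lsqnonneg`). In `fit_condition`, a negative non-water weight
  suppresses the concentration table (with a warning) instead of aborting
  the run, so the weights and residual diagnostics of a marginal fit
  remain inspectable.
* **Collinearity.** The design-matrix condition number is always computed
  and attached; above $10^8$ a warning is recorded, but the solve is never
  refused.

Fit quality is the fraction of wavelengths at which the reconstruction
lies within one sample SD of the mean ("within-SD fraction"). At
wavelengths where the SD is exactly zero the reconstruction must match the
mean to $10^{-9}$ — exact equality is the only sensible reading of a
zero-width envelope, and the tolerance absorbs floating-point noise.

## The concentration conversion

Tissue water content is anchored at a fixed volume fraction — 77% for
kidney, a figure measured in rat and adopted for human tissue in the
absence of a species-specific value; it is a configurable argument, not a
constant. The remaining volume is shared among the non-water chromophores
proportionally to their weights:

$$c_\text{water} = W, \qquad
  c_i = \frac{w_i}{\sum_{j \ne \text{water}} w_j}\,(100 - W), \qquad W = 77.$$

The water weight itself never enters the denominator: water is anchored,
not allocated. This rule conserves volume exactly (the table always sums
to 100% before rounding), is invariant to a common rescaling of the
non-water weights — which is why the normalized-library convention does
not distort concentrations — and reproduces, from the published healthy
and CRCC kidney weight sets (`reference_weights()`), every reference
concentration at the 2-decimal reporting precision (see
`tests/testthat/test-acceptance.R`). Concentrations are volumes, so
negative weights are rejected here with a pointer to the constrained fit.
Reporting rounds to 2 decimals; comparisons between conditions label each
chromophore increased/decreased/unchanged at that reporting precision
while returning unrounded differences.

## The synthetic-data generator

No measurement cohort ships with the package, so a generator stands in
for one, with two distinct jobs: providing a realistic chromophore
library, and forward-generating measurement cohorts with known ground
truth.

**Library.** Each of the eight components is a sum of parametric bands:
Gaussians $a\,e^{-(\lambda-c)^2/2\sigma^2}$ at the landmark positions
(water 980 nm, DNA 260 nm, proteins 230 nm, HbO2 415/540/570 nm, Hb 415 nm
plus a single visible band at 555 nm to distinguish it from HbO2, lipids
930 nm with the zero-below-620 nm convention applied), and exponential
decays $a\,e^{-k(\lambda-200)}$ for the pigment baselines, melanin
($k = 0.011$/nm) steeper than lipofuscin ($k = 0.0055$/nm). Widths and
decay constants were chosen once for qualitative resemblance to published
curves — distinct, physically plausible band shapes giving a full-rank
design (condition number ≈ 24 on the default grid) — and are configurable
through `band_model`; they make no claim of quantitative fidelity to any
measured spectrum.

**Cohorts.** The true spectrum is $X w^\ast$ with $w^\ast$ defaulting to
the healthy-kidney reference weights rescaled by a single common factor so
that $\max(\mu_a) \cdot d = 0.9$ (the slab relation is only physical while
$\mu_a d \le 1$; common rescaling leaves concentrations untouched). Each
sample's $T_t$/$R_t$ is the exact slab inverse plus independent additive
Gaussian noise (default SD $10^{-3}$) applied in *measurement space* —
where noise arises in a real acquisition — then clipped into $[0,1]$ with
clip events counted. Default cohort size is 10 samples of 0.5 mm slabs.
The split of unabsorbed light into transmitted and reflected shares
(default 0.4 reflected) cannot affect any result, since only the sum
enters the absorption formula; a test asserts this.

**What passing synthetic tests does not show.** The generator emulates
band positions, pigment baselines, cohort structure, and
measurement-space noise. It does not emulate scattering, sphere geometry,
wavelength-dependent instrument response, spectrally correlated noise, or
the bound-water band narrowing seen in real tissue near 980 nm — real
water in tissue is largely bound and absorbs in a narrower band than the
pure-liquid spectra libraries are built from, which is the known
weak spot of the reconstruction around 980 nm. Recovery results on
synthetic cohorts therefore validate the estimator and the pipeline
plumbing, not the biological fidelity of any particular library.

## Numerical choices and degenerate inputs

* Interpolation between library grids is piecewise linear: no spline
  overshoot, and non-negativity between non-negative knots is guaranteed.
  Wavelengths outside a source spectrum's support are zero-filled and
  annotated (the same handling applied to lipids below their data limit).
* Normalization endpoints are exact: `(v - min)/(max - min)` yields
  literal 0 and 1, asserted to $10^{-12}$; constant spectra are a named
  error rather than a silent division by zero.
* Measurement CSVs are written at 15 significant digits so that a
  noiseless simulate-write-read-fit round trip recovers weights to
  $10^{-6}$; human-facing summaries use 6 significant digits. Output files
  are byte-stable across reruns and stamped with a configuration hash and
  the package version, never with timestamps.
* Problem sizes in the test suite are the study conditions themselves:
  801-point grids, 8 components, cohorts of 10, noise SDs
  $\{0, 10^{-3}, 10^{-2}\}$, 20 seeds for the recovery experiment —
  small enough to run in seconds, large enough to be the actual analysis
  scale rather than a toy.

## Known limitations

The slab formula is an energy balance, not radiative transfer; absolute
$\mu_a$ values inherit its bias, though unmixing weights — ratios against
a shared library — are less sensitive. Plain least squares can go negative
for trace components at realistic noise; the constrained solver is one
flag away. The 77% water anchor is an assumption carried across species
and conditions, and the concentration table is exactly as good as that
anchor. Pigment baselines (melanin vs lipofuscin) are the most mutually
collinear library pair, and their individual weights are the least stable
under noise — their sum is considerably better determined.
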