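# chromounmix

Linear spectral unmixing of broadband tissue absorption spectra, with a
water-anchored conversion of the fitted chromophore weights into volume
concentrations. The package targets diagnostic tissue spectroscopy — its
reference application is discriminating healthy from chromophobe renal cell
carcinoma (CRCC) human kidney tissue from integrating-sphere measurements of
thin slabs — but every stage is generic over user-supplied chromophore
libraries, wavelength grids, and tissue conditions.

## The method

For a thin slab of thickness *d* (cm), treating all light that is neither
transmitted nor reflected as absorbed, the absorption coefficient follows
directly from the total transmittance *T*<sub>t</sub>(λ) and total
reflectance *R*<sub>t</sub>(λ):

    mu_a(lambda) = (1 - (T_t(lambda) + R_t(lambda))) / d        [1/cm]

Per-sample spectra of one tissue condition are aggregated into a
per-wavelength mean and sample standard deviation. The mean spectrum *y* is
then decomposed as a weighted sum over a library of chromophore absorption
spectra (water, melanin, lipofuscin, DNA, HbO2, Hb, proteins, lipids — each
0–1 normalized so the weights share a scale):

    mu_a(lambda) = sum_i w_i mu_a,i(lambda)

with the weights *b* = (w₁, …, w₈) estimated by least squares,

    b = (X'X)^-1 X'y

where column *i* of the design matrix *X* holds μ<sub>a,i</sub> on the
shared 200–1000 nm grid (the production solver uses a QR factorization; the
normal-equations form above is kept as a cross-check). Fit quality is
scored as the fraction of wavelengths at which the reconstruction stays
within the ±SD envelope of the mean experimental spectrum.

Finally, weights become volume concentrations by anchoring tissue water at
a fixed fraction (77% for kidney) and sharing the remaining volume among
the non-water chromophores in proportion to their weights:

    c_water = 77%,   c_i = w_i / sum_{j != water} w_j * 23%

A parametric synthetic-data module (Gaussian bands at the landmark
positions — proteins ~230 nm, DNA ~260 nm, hemoglobin Soret 415 nm and
Q-bands 540/570 nm, lipids ~930 nm, water 980 nm — plus exponentially
decaying pigment baselines) forward-generates measurement cohorts with
known ground truth so the whole pipeline is testable without any data
downloads.

## Worked example

Convert the published healthy-kidney weight set into concentrations:

```r
library(chromounmix)
weights_to_concentrations(reference_weights("healthy"), condition = "healthy")
#> condition: healthy
#>   component weight concentration_pct
#>       water  14.47             77.00
#>     melanin   1.00              0.09
#>  lipofuscin   5.65              0.51
#>         DNA  14.55              1.32
#>        HbO2 193.21             17.53
#>          Hb  37.28              3.38
#>    proteins   1.71              0.16
#>      lipids   0.07              0.01
#> total: 100%
```

Water is fixed at 77% of tissue volume; the other entries share the
remaining 23% in proportion to their fitted weights, so HbO2 (weight
193.21, by far the dominant absorber) accounts for 17.53% of the volume
and trace lipids round to 0.01%.

Run the full pipeline on a simulated 10-sample cohort with measurement
noise:

```r
lib <- make_default_library()
coh <- generate_cohort(synthetic_scenario(seed = 1, n_samples = 10, noise_sd = 1e-3), lib)
fit_condition(coh$measurements, lib)
#> <unmixing_result> 'synthetic': n = 10 samples, rmse 0.008953 1/cm, within-SD fraction 0.983, cond(X) 24.4
#> weights:
#>        water      melanin   lipofuscin          DNA         HbO2           Hb
#>  1.122527005  0.064209170  0.447053043  1.127043649 14.967762746  2.891444076
#>     proteins       lipids
#>  0.136912629  0.004300155
```

The reconstruction stays inside the SD envelope at 98.3% of wavelengths,
and the recovered weights match the generating truth (the healthy
reference composition rescaled into the physical range of the slab model)
to within a few percent for every non-trace component; the derived
concentration column reproduces the healthy reference values.

A thin command-line wrapper with `simulate`, `mua`, `fit`,
`concentrations`, and `compare` subcommands is installed under
`inst/cli/chromounmix`.

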