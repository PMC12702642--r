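Package: chromounmix
Title: Chromophore Unmixing of Broadband Tissue Absorption Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes broadband absorption coefficient spectra of thin tissue
    slabs from integrating-sphere total transmittance and total reflectance
    measurements, decomposes them as a weighted sum of chromophore absorption
    spectra (water, melanin, lipofuscin, DNA, oxygenated and deoxygenated
    hemoglobin, proteins, lipids) by least squares, and converts the fitted
    weights into volume concentrations anchored on a fixed tissue water
    fraction. Includes a parametric synthetic-spectra generator so the whole
    pipeline can be exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
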