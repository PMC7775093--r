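Package: humol
Title: Molecular-Composition Model Linking CT Number, Mass Density, and
    Electron Density
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative CT tools for radiotherapy physics built around a
    four-component (water/lipid/protein/mineral) molecular model of the
    relationship between CT Hounsfield units, mass density, and electron
    density relative to water.  Provides the mass-density-normalized HU
    transform and its closed-form inverses, spectrum-weighted mass-attenuation
    physics with an XCOM-style elemental attenuation table, two calibration
    routes for the empirical model coefficients (x-ray spectrum based and
    phantom-scan based), the clinical piecewise-linear HU calibration
    baseline, a composition-error sensitivity analysis, first-order
    uncertainty propagation for phantom ground truths, synthetic voxel
    phantom generation, voxelwise HU-to-density conversion, and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
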