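Package: vesiform
Title: Biophysical Characterization of Protein-Loaded Lipid Vesicles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable analysis pipeline for the multi-technique
    biophysical characterization of large unilamellar vesicles (LUVs) and
    proteo-LUVs. Implements small-angle X-ray scattering (SAXS) bilayer
    form-factor fitting with a three-Gaussian electron-density model,
    hollow-sphere fitting of multi-angle static light scattering (MALS)
    Rayleigh ratios, smoothing-constrained regularized inversion of dynamic
    light scattering (DLS) autocorrelation functions with intensity-to-mass
    reweighting, model-mediated fusion of MALS and SAXS branches into a
    whole-liposome form factor, and fluorometric loading quantification
    (calibration curves, drug loading and loading efficacy percentages,
    Laurdan generalized polarization, ANS-based critical micelle
    concentration). A synthetic-data module generates every input the
    pipeline consumes so that all stages are testable without instrument
    data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    pracma,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
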