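# vesiform

Multi-technique biophysical characterization of large unilamellar vesicles
(LUVs) and protein-loaded proteo-LUVs, in R.

Drug-delivery and membrane-biophysics labs routinely characterize extruded
liposome preparations with a battery of scattering and fluorescence
measurements: small-angle X-ray scattering (SAXS) for the bilayer's internal
structure, multi-angle static light scattering (MALS) and dynamic light
scattering (DLS) for overall size, and fluorometric assays for how much
cargo actually ended up inside. `vesiform` implements that whole analysis
chain as tested, reusable functions, together with synthetic-data
generators so every stage can be exercised and validated without any
instrument files.

## What it computes

**SAXS bilayer fitting.** Dilute unilamellar vesicles scatter as
*I(q) = s |F(q)|² / q²*, where *F* is the radial Fourier transform of the
bilayer electron density. The density is modeled as three Gaussians riding
on a sphere of radius *R*:

    rho(r) = sum_k rho_k exp(-(r - R - eps_k)^2 / (2 sigma_k^2)),  k = 1..3

with the hydrophobic core fixed at `eps_1 = 0, rho_1 = 1` (the contrast
normalization) and the inner/outer head-group layers at `eps_2 < 0 <
eps_3`. The head-to-head bilayer thickness is `d = eps_3 - eps_2`. The
closed-form amplitude (extended-domain Gaussian integrals, valid for
`sigma << R`) is fitted to a curve by multi-start Levenberg–Marquardt
(`fit_saxs()`), reporting *R*, *d*, the full electron-density profile and
Jacobian-based uncertainties.

**MALS hollow-sphere fitting.** Rayleigh ratios (toluene-normalized,
`to_rayleigh()`, R_tol = 28e-6 cm⁻¹) are fitted with a uniform spherical
shell of fixed thickness (4 nm, the SAXS-derived bilayer thickness) for the
vesicle radius and its radius of gyration (`fit_mals()`).

**DLS inversion.** Intensity autocorrelations are converted through the
Siegert relation and inverted into decay-rate/size distributions by
smoothing-constrained (CONTIN-style) nonnegative regularization with
L-curve smoothing selection (`invert_dls()`), plus intensity → mass/number
reweighting for thin-shell vesicles (`reweight()`).

**MALS/SAXS fusion.** The two q ranges (5–25 μm⁻¹ and 0.1–5 nm⁻¹) do not
overlap; `sew()` joins them into a single whole-liposome form factor
*P(q)*, bridging the gap through the fitted Gaussian-shell model.

**Loading fluorometrics.** Calibration lines, degree-of-labeling-corrected
protein quantification, drug loading `DL% = 100 c_drug/c_lipid` and
loading efficacy `LE% = 100 m_drug,final/m_drug,offered`, Laurdan
generalized polarization `GP = (I435 - I500)/(I435 + I500)`, ANS-based
critical micelle concentration breakpoints, and A280 Beer–Lambert
conversion.

## Worked example

```r
library(vesiform)

# a 46 nm vesicle with a 3.9 nm bilayer, and its scattering curve
truth <- lip0_profile()
curve <- gen_saxs(truth, scale = 3.7)

fit <- fit_saxs(curve, n_restarts = 8, seed = 1)   # default generic init
fit
#> Gaussian-shell SAXS fit
#>   R = 45.999 +/- 0.000435 nm
#>   d = eps_3 - eps_2 = 3.871 +/- 0.00157 nm
#>   chi2_reduced = 2065 | converged: TRUE | restarts: 8

fit_mals(gen_mals(lip0_mals_model(), amplitude = 2e-5), init_R = 30)
#> Hollow-sphere MALS fit
#>   R_mid = 41.500 +/- 1.06e-12 nm (t fixed at 4.00 nm)
#>   Rg = 41.580 nm | chi2_reduced = 2.771e-37 | converged: TRUE

loading_percentages(prep_spec())
#> Loading report: DL% = 0.045, LE% = 0.45, loaded = 3.81 nM
```

The SAXS fit recovers the generating radius (46 nm) and bilayer thickness
(3.9 nm, here to 0.7% from a deliberately generic starting guess — an
initial profile within ±20% of the truth recovers both to machine
precision); the MALS fit recovers the shell radius
(41.5 nm) with its radius of gyration; the loading report turns the
reference preparation's mass balance (3 mg lipid film, 0.5 mL of 0.2 mg/mL
protein, 5 mL final volume at 0.2 mg/mL lipid and 9e-5 mg/mL protein,
23.6 kDa) into a drug loading of 0.045%, a loading efficacy of 0.45% and a
3.8 nM encapsulated concentration.

A full pipeline run over synthetic fixtures:

```r
run_pipeline(list(seed = 1, stages = c("saxs", "mals", "dls", "fusion", "loading")),
             output_dir = "out")   # writes out/report.json, out/composite.csv
```

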