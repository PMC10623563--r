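---
title: "Models and methods for vesicle scattering and loading analysis"
author: "vesiform"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for vesicle scattering and loading analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesiform)
```

`vesiform` bundles the analyses used to characterize extruded large
unilamellar vesicles (LUVs) and their protein-loaded counterparts: SAXS
bilayer fitting, MALS hollow-sphere fitting, DLS inversion, form-factor
fusion, and loading fluorometrics. This vignette is the package's own
account of the underlying models, the numerical choices made, and what the
synthetic-data tests do and do not demonstrate.

## The Gaussian-shell SAXS model

A dilute suspension of unilamellar vesicles with radius much larger than
the bilayer thickness scatters X-rays as

$$I(q) = s\,\frac{|F(q)|^2}{q^2},$$

where $F(q)$ is the radial Fourier transform of the electron-density
contrast of the bilayer and the scale $s$ absorbs number density and
instrument calibration. The contrast profile across the bilayer is a sum of
three Gaussians on a sphere of mid-bilayer radius $R$: a hydrophobic core
(component 1) and the inner and outer polar head layers (components 2
and 3),

$$\rho(r) = \sum_{k=1}^{3} \rho_k
  \exp\!\left[-\frac{(r - R - \epsilon_k)^2}{2\sigma_k^2}\right].$$

The core fixes the gauge: $\epsilon_1 = 0$ places the bilayer center,
$\rho_1 = 1$ normalizes the (relative) contrast scale. Without this the
model has an exact scale degeneracy with $s$ and a sign degeneracy
($\rho \to -\rho$ leaves $I$ unchanged). The head-to-head bilayer thickness
is $d = \epsilon_3 - \epsilon_2$.

Extending each radial integral over $(-\infty, \infty)$ gives the closed
form

$$F(q) = \frac{4\pi}{q}\sqrt{2\pi}\sum_k \rho_k \sigma_k
  e^{-q^2\sigma_k^2/2}\left[r_k \sin(q r_k) + q\sigma_k^2 \cos(q
  r_k)\right], \qquad r_k = R + \epsilon_k,$$

exact in the limit $\sigma_k \ll R$. For the systems this package targets
($\sigma \sim 0.3$–$1$ nm against $R \sim 45$ nm) the truncation error is
below $10^{-3}$ relative; the test suite pins the closed form against
adaptive quadrature of the same density at that tolerance, and
`gaussian_shell_amplitude()` warns when $\sigma_k > R/3$. Three Gaussians
are the minimal parameterization that reproduces the observable features of
vesicle curves (node positions and strengths, head-group asymmetry);
the constructor accepts other component counts, but all defaults and
fixtures use three.

Radius polydispersity is deliberately not modeled: the single-$R$ model is
the minimal one, the nodes of real extruded preparations are already well
captured by it, and a smearing hook would trade transparency for two extra
correlated parameters.

### Fitting strategy

`fit_saxs()` minimizes weighted least squares ($1/\sigma^2$ weights when
the curve carries uncertainties, unweighted otherwise) over the free
parameters $R, \rho_2, \rho_3, \epsilon_2, \epsilon_3, \sigma_{1..3}$ and
$\log s$, in the window $0.1 \le q \le 5$ nm$^{-1}$ where the dilute
thin-shell expression is valid. Three practical problems shape the
implementation:

* **Multimodality in $R$.** The vesicle radius sets the phase of the
  low-$q$ oscillations; displacing $R$ by half an oscillation period
  creates a deep false minimum. Each optimizer start therefore begins with
  a coarse 1-D scan of $R$ (±25%, 161 points) before any gradient step.
* **Nine intensity decades.** The unweighted objective is numerically
  dominated by the lowest-$q$ points. Each start is first refined on
  floored log-intensity residuals, which see every decade, then polished
  with the contract weights. The polish is run both from the scanned start
  and from the log-stage optimum and the better minimum kept, because the
  log-stage optimum can sit on a spurious stationary point of the weighted
  objective.
* **Head-group permutation.** Swapping the two head Gaussians leaves the
  model invariant; results are canonicalized so $\epsilon_2 < 0 <
  \epsilon_3$ (inner head inside, outer head outside).

The fit is multi-start (default 8 restarts, ±20% uniform perturbations,
seeded). Standard errors come from the Jacobian at the optimum; over 100
simulated 2%-noise replicates these are calibrated (all parameters within
3 reported standard errors of truth in ≥95% of replicates — the test suite
re-measures this). Near-optimal restarts that disagree on $d$ beyond the
reported uncertainty flag the result as multimodal. The default initial
guess ($R = 45$ nm, $d = 4$ nm, head widths 0.5 nm) is a
bilayer-physics-informed convention, not an estimate from the data. A fit
that stops on the iteration limit with a residual below $10^{-10}$ of the
data's scale is reported as converged: on noise-free data the optimizer
oscillates numerically at an essentially exact solution.

## The MALS hollow-sphere model

Static light scattering sees the whole vesicle as a spherical shell of
uniform contrast between $R_i = R_{mid} - t/2$ and $R_o = R_{mid} + t/2$:

$$P(q) = \left[\frac{V_o f(qR_o) - V_i f(qR_i)}{V_o - V_i}\right]^2,
 \qquad f(x) = 3\,\frac{\sin x - x\cos x}{x^3},$$

normalized to $P(0) = 1$, with radius of gyration $R_g^2 =
\tfrac{3}{5}(R_o^5 - R_i^5)/(R_o^3 - R_i^3)$. Counts are converted to
Rayleigh ratios against the toluene reference ($R_{tol} = 28\times10^{-6}$
cm$^{-1}$) after solvent subtraction. `fit_mals()` floats only $R_{mid}$
and one multiplicative amplitude over the instrument window 5–25
μm$^{-1}$; the thickness is a fixed input (default 4 nm, consistent with
the SAXS thickness) because a 4 nm shell on a 40+ nm sphere leaves $t$ and
the amplitude nearly degenerate at these $q$. No background term is
floated; a background option would be the first thing to add for
instruments with stray-light issues. Flat curves are flagged
non-identifiable rather than fitted.

## DLS inversion

The measured intensity autocorrelation is related to the field correlation
by the Siegert relation $g_2(\tau) - 1 = \beta |g_1(\tau)|^2$. The
coherence factor $\beta$ is taken from the short-lag plateau when not
supplied. A polydisperse population gives $g_1(\tau) = \sum_j w_j
e^{-\Gamma_j \tau}$, inverted by smoothing-constrained regularization:

$$\min_{w \ge 0}\; \|K w - g_1\|^2 + \lambda \|L_2 w\|^2,$$

with $K_{ij} = e^{-\Gamma_j \tau_i}$ and $L_2$ the second-difference
operator. The nonnegative solution is computed by Lawson–Hanson NNLS on
the stacked system (`pracma::lsqnonneg`). The second-difference smoothing
operator is a documented choice among CONTIN-style regularizers, and
$\lambda$ is selected at the L-curve corner (maximum discrete Menger
curvature of $\log\|Kw - g_1\|$ versus $\log\|L_2 w\|$) unless given.

Decay rates map to hydrodynamic radii by Stokes–Einstein, $R_h = k_B T
q^2 / (6\pi\eta\,\Gamma)$, with defaults $T = 293.15$ K and $\eta = 1.002$
mPa·s (water at 20 °C, matching the SAXS measurement temperature; the
instrument constants are all overridable). The default radius grid is 100
log-spaced points over 5–500 nm — an order of magnitude on either side of
the 50 nm extrusion pore scale.

Two practical details matter for accuracy. First, lags where the
correlation has decayed into the baseline noise are dropped before
inversion (`trim_tail`): the square-root in the Siegert transform is
biased upward on pure noise and would otherwise be fitted as a spurious
slow mode — in testing this artifact displaced the recovered median by
~10%. Second, distributions carry an explicit weighting basis. The
inversion natively yields intensity weights, $w_I \propto n\,m^2 P(q,R)$;
with the thin-shell mass scaling $m \propto R^2$ (vesicles are shells of
fixed thickness, not filled spheres; the exponent is switchable),
intensity → mass is division by $m\,P(q,R)$ and intensity → number by
$m^2 P(q,R)$, with $P$ evaluated as a hollow sphere at the measurement
$q$. Bins where $P$ vanishes are excluded with a warning rather than
amplified.

## Sewing MALS and SAXS into one form factor

The MALS (5–25 μm$^{-1}$) and SAXS (0.1–5 nm$^{-1}$) ranges are disjoint,
so no data-overlap scaling exists; the join is anchored through the fitted
models instead. The whole-liposome form factor predicted by the fitted
Gaussian shell, $P(q) = |F(q)|^2/|F(0)|^2$, bridges the gap. Because the
measured SAXS intensity carries the thin-shell $1/q^2$ factor, the SAXS
branch is mapped to form-factor space as $q^2 I(q)$ before the scale

$$\alpha = \arg\min_\alpha \sum_{q \in W}\left[\alpha\,q^2 I(q) -
P(q)\right]^2$$

is fitted over the bridging window $W = [0.1, 0.3]$ nm$^{-1}$
(configurable; the low-$q$ end of the SAXS window, where both models
describe the same smooth envelope). The MALS branch is normalized by its
fitted hollow-sphere amplitude, so $P \to 1$ as $q \to 0$. The operation
is idempotent (re-sewing a sewed branch returns $\alpha = 1$), keeps
per-point provenance, and rejects non-positive optimum scales as input
sign errors.

## Loading fluorometrics

All quantities are plain, auditable arithmetic:

* calibration lines by OLS (`fit_calibration()`), inverted and divided by
  the degree of labeling for protein quantification (`quantify_loaded()`);
  the DOL itself is an input — kit-specific extinction constants are not
  hard-coded;
* $DL\% = 100\,c_{drug}/c_{lipid}$ (mass basis, lipid denominator;
  the drug/(drug+lipid) convention is available and differs only beyond
  the third decimal at these loadings) and
  $LE\% = 100\,(c_{drug}V_{final})/(c_{hyd}V_{hyd})$, plus the molar
  concentration $c_{drug}/MW$ (`loading_percentages()`). The reference
  preparation (3 mg film, 0.5 mL of 0.2 mg/mL protein, 5 mL final at
  0.2 mg/mL lipid and $9\times10^{-5}$ mg/mL protein, 23.6 kDa) gives
  $DL\% = 0.045$, $LE\% = 0.45$ and 3.8 nM;
* Laurdan generalized polarization $GP = (I_{435} -
  I_{500})/(I_{435}+I_{500})$, bounded in $[-1,1]$, from point intensities
  at the two canonical wavelengths (nearest grid point within 1 nm;
  band-integrated windows would be the alternative had the convention been
  stated);
* CMC as the breakpoint of a continuous two-segment piecewise-linear fit:
  exhaustive screening of interior candidate breakpoints, golden-section
  refinement of the best, accepted only if an F-test against a single line
  rejects at $\alpha = 0.05$ ("no CMC detected" otherwise). Exhaustive
  search plus refinement is robust for the short titration series typical
  of these assays.

## The synthetic-data module

Every estimator in the package has a paired generator (`gen_saxs()`,
`gen_mals()`, `gen_dls()`, `gen_calibration()`, `gen_laurdan()`,
`gen_cmc()`), each a deterministic function of (truth, seed). Noise models
are Gaussian-relative, Gaussian-absolute or Poisson-like; zero noise
returns the model exactly, and every generator/estimator pair closes its
round trip exactly at zero noise (the Laurdan generator solves the 2×2
band-overlap system so the target GP is hit exactly, not approximately).

The canonical fixtures are an unloaded-vesicle-like geometry ($R = 46$ nm,
$d = 3.9$ nm; MALS shell radius 41.5 nm) and a loaded-vesicle-like one
($R = 52$ nm, $d = 3.9$ nm, heavier outer head layer; MALS 46.5 nm),
with shell thickness 4 nm — the reference best-fit values, so the
recovery tests are self-describing. The contrast signs (positive core,
negative heads, under the $\rho_1 = 1$ gauge) and widths
($\sigma \approx 0.45$–0.9 nm) are conventional phospholipid-bilayer
magnitudes chosen once for the fixtures.

What the synthetic tests demonstrate: correctness of the closed forms
(against quadrature oracles), of the estimators (parameter recovery,
calibrated uncertainties at 2% noise, delta and bimodal spectrum
recovery, 10%-accurate median recovery at SNR 100), and of all the
plumbing (units, bases, round trips, determinism). What they do not
demonstrate: robustness to the pathologies of real instrument data —
resolution smearing, multilamellar contamination, dust in DLS, stray
light in MALS, inner-filter effects in fluorescence. The generators
emulate idealized instruments on purpose; the estimators' behavior under
those pathologies must be judged on real data.

## Problem sizes and numerical conventions

The simulation studies run at deliberately moderate sizes — 400-point SAXS
curves, 40-point MALS curves, 120-lag DLS traces, 100 noisy replicates for
the coverage study — which keep each fit under a couple of seconds while
leaving the estimators' asymptotics clearly visible. Momentum transfer is
stored in nm$^{-1}$ everywhere, converted on ingestion (μm$^{-1}$ ×
$10^{-3}$); lag times in seconds; radii in nm; concentrations in mg/mL
(= g/L) with kDa molar masses. Degenerate inputs fail loudly and early:
non-increasing abscissae, negative uncertainties, zero-intensity GP
spectra, singular calibration designs, flat MALS curves, all-zero DLS
spectra, non-positive sewing scales.

## Known limitations

* The SAXS stage models a single vesicle radius (no polydispersity or
  resolution smearing) and a three-Gaussian bilayer; strongly asymmetric
  or multilamellar systems need a different model.
* The MALS stage does not model the refractive-index increment, so its
  amplitude is a nuisance parameter, not a molar mass.
* The DLS regularizer is one member of the CONTIN family; other smoothing
  operators or weightings will move individual weights (though not the
  gross features) of the recovered distribution.
* The sewing scale is model-mediated by construction; it is only as good
  as the fitted bridge model in the window.
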