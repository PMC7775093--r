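---
title: "The molecular model behind humol: methods, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The molecular model behind humol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(humol)
```

## The model and its assumptions

CT scanners report Hounsfield units,
\[
\mathrm{HU} = 1000\,(\mu_x - \mu_w)/\mu_w ,
\]
a ratio of *linear* attenuation coefficients, which entangle two distinct
things: how dense a voxel is, and what it is made of.  `humol` works with the
mass-density-normalized CT number
\[
\mathrm{HU}_\rho = 1000\,\frac{(\mu/\rho)_x - (\mu/\rho)_w}{(\mu/\rho)_w}
                 = \frac{\mathrm{HU} + 1000}{\rho} - 1000 ,
\]
built from *mass* attenuation coefficients.  $\mathrm{HU}_\rho$ is an
intrinsic material property: it depends only on elemental composition and
the beam spectrum, never on density.  The pair of identities
\[
\rho = \frac{\mathrm{HU}+1000}{\mathrm{HU}_\rho+1000}, \qquad
\rho_e = \rho \cdot \frac{\sum_i \omega_i Z_i/A_i}{(Z/A)_w}
\]
then converts a measured CT number to mass density and electron density
once $\mathrm{HU}_\rho$ and the Z/A-weighted electron ratio are known.

The modeling assumption that makes this practical is the **four-component
tissue model**: biological tissues are mass-fraction mixtures of water,
lipid, protein and mineral (hydroxyapatite, Ca$_5$(PO$_4$)$_3$OH).  Because
mass attenuation and Z/A both obey the mixture rule, each is *affine* in the
molecular fractions $\omega$:
\[
\mathrm{HU}_\rho = \omega_l \alpha_1 + \omega_p \alpha_2 + \omega_m \alpha_3,
\qquad
\rho_e/\rho = 1 + \omega_l \beta_1 + \omega_p \beta_2 + \omega_m \beta_3 .
\]
Water carries no term in either sum — it *is* the reference, so both
relations pass through the origin by construction.  This is why every
regression in the package is fitted **without an intercept**: a free
intercept would let the fit drift off the water reference that the HU scale
itself defines.

The $\alpha_i$ are beam-specific (the photoelectric component of attenuation
falls steeply with energy, so mineral's $\alpha_3$ swings from roughly +600
at 120 kVp to about −78 at 3.5 MV); the $\beta_i$ are beam-independent
Z/A arithmetic.

What the model does *not* cover: beam hardening, scatter, detector response,
or any scanner simulation — measured mean HU per material/voxel is an input.
It also does not attempt to determine the molecular composition itself;
composition is an input, and the sensitivity machinery quantifies what an
error in it costs.

## Parameters and how they are calibrated

**`alpha` (HU units, per beam).**  Two routes are implemented, and they
cross-validate each other:

1. *Spectrum route* (`alpha_from_spectrum()`):
   $\alpha_i = 1000\,((\mu/\rho)_i/(\mu/\rho)_w - 1)$ with each $\mu/\rho$
   averaged over the beam's fluence spectrum using the bundled XCOM-style
   elemental attenuation table and the mixture rule.
2. *Phantom route* (`fit_alpha_from_phantom()`): compute $\mathrm{HU}_\rho$
   for each insert of a scanned calibration phantom from its measured HU and
   known density, then solve the no-intercept, **unweighted** ordinary
   least-squares problem $\mathrm{HU}_\rho \sim \omega_l + \omega_p +
   \omega_m$.  Unweighted OLS reproduces the reference coefficients from the
   bundled phantom table's rounded data (verified against the normal
   equations in the test suite), and nothing in the calibration setup
   motivates heteroscedastic weights.

On the bundled nine-insert phantom the two routes agree: the phantom route
gives (−50.8, −58.1, 604.8) at kV and (4.5, −54.1, −77.9) at MV, while the
spectrum route with hydroxyapatite as the mineral gives $\alpha_3 = 632$ (kV)
and $-75$ (MV).  Materials whose lipid/protein/mineral fractions are all zero
(water inserts) exert no leverage on a no-intercept fit; their residuals
report how far the phantom's "solid water" sits from true water.

**`beta` (dimensionless, beam-independent).**  Analytically,
$\beta_i = (Z/A)_i/(Z/A)_w - 1$ from the bundled atomic constants
(`beta_analytic()`); hydroxyapatite gives −0.103.  Empirically,
`fit_beta_from_tissues()` regresses elemental-route electron ratios of a
tissue table on molecular fractions, intercept fixed at one.  The package
ships reference values (0.00499, −0.0419, −0.113) from such a regression
over a standard human-tissue compilation (`reference_beta()`).  Because
$\rho_e/\rho$ is linear in $\omega$, its composition sensitivity is exact
and tiny for soft tissue: $|\beta_i| \times 0.01$ per percentage point —
0.00005 (lipid), 0.00042 (protein), 0.0011 (mineral).

**QC threshold.**  Surrogate inserts with ≥ 1% chlorine by mass (some lung
surrogates) sit off the biological-molecule manifold and are flagged by
`qc_flag_materials()`; the threshold is inclusive and configurable, and
flagged materials are retained in reports so exclusions stay auditable.

## Beam spectra

Spectra are inputs, not products, of the package.  Two constructors cover
the common cases:

* `filtered_kramers_spectrum()` — the bundled example kV beam: Kramers
  bremsstrahlung $(kVp - E)/E$ for a 120 kVp tube hardened through 1.25 mm
  of copper (attenuated with the bundled Cu $\mu/\rho$ curve) on a 1 keV
  grid from 20 keV.  Mean energy 78 keV.  A measured or externally computed
  spectrum can be supplied as a two-column CSV via `read_spectrum()`.
* `gamma_spectrum()` — the MV beam as a gamma probability density sampled on
  a grid.  Defaults: shape 1.5, grid 100–3000 keV, scale solved so the
  grid-weighted mean is 860 keV.  Shape 1.5 puts the spectral mode near
  0.29 MeV, the qualitative shape of published 3.5 MV fan-beam MVCT
  spectra, and the 100 keV grid floor reflects target/filter self-absorption
  — with fluence extended to very low energies, the photoelectric divergence
  of calcium would dominate the spectral average unphysically.

The spectrum-route mineral checks (kV ≈ 630 vs 629.9 reference, MV ≈ −75 vs
−76.7) are held to a ±5% band in the tests, deliberately soft: they probe
spectrum fidelity, and neither clinical beam is fully specified by a mean
energy alone.

The elemental attenuation fixture covers H, C, N, O, P, S, Ca (and Cu for
filtration) on the standard published 10 keV–3 MeV grid, interpolated
log-log linearly, XCOM practice.  None of these elements has an absorption
edge in the imaging range.

## Sensitivity analysis

`composition_error()` answers: if a voxel is converted assuming composition
A while it is truly composition B, what happens to ρ and ρ_e?  The true
material is "imaged" noiselessly through the forward model
(`simulate_hu()`), then converted with the assumed composition.  Percent
errors are reported as $100\,(\hat{x} - x)/\hat{x}$ — normalized by the
*estimate* — which is the convention under which the full 12-row
pure-composition/10%-contamination grid (`sensitivity_grid()`) reproduces
the reference sensitivity table cell-for-cell (the swapped reading,
normalizing by the truth with assumed and true roles exchanged, gives the
same numbers).  Two structural facts, both asserted as tests: the errors are
invariant to the true density (it cancels between simulation and
estimation, so the grid's choice of 1 g/cc is a convenience, not an
assumption), and in the small-contamination limit they scale linearly,
with the ρ_e-vs-ρ gap governed exactly by $|\beta|$.

`propagate_ground_truth_uncertainty()` is first-order (delta-method)
propagation for phantom ground truths, all sources independent:
$(\sigma_\rho/\rho)^2 = (\sigma_m/m)^2 + (\sigma_V/V)^2$, and
$\sigma_r^2 = \sum_i (\sigma_{\omega_i} Z_i/A_i)^2/(Z/A)_w^2$ for the
electron ratio, combined in quadrature for ρ_e.  The propagation formulas
are a documented package choice; with per-mil scale measurement inputs they
give the few-per-mil density uncertainties typical of a carefully assayed
phantom material.  Nothing beyond first order (no Monte-Carlo posterior) is
attempted.

## Fixtures and the synthetic phantom

Bundled fixtures (`load_fixture()`): the nine-insert CIRS-style calibration
phantom table (`table1`), the four-material in-house tissue-mimicking
phantom table with ground truths and imaging-derived values (`table2`), a
four-entry molecule library (`molecules`), a reference tissue table
(`tissues`), the attenuation table, and the example kV spectrum.  Three
fixture caveats, each deliberate:

* `table1`'s electron-density column derives from the manufacturer's
  undisclosed elemental data; it is carried as data (the piecewise-linear
  baseline needs it) and never recomputed.
* The molecule library's lipid (triolein-like, H .118/C .773/O .109) and
  protein (gelatin-like CHNOS) entries are representative literature-style
  compositions — the physical phantom's coconut oil and porcine gelatin were
  characterized by combustion analysis whose raw values are not public.  No
  hard test depends on their exact values.
* The tissue table is **synthetic**: named representative tissues expressed
  as mixtures of the molecule library, with elemental compositions derived
  at load time.  Its electron ratios are therefore *exactly* affine in the
  molecular fractions, so `fit_beta_from_tissues()` recovers the molecule
  library's analytic betas with $R^2 = 1$ — a recovery check, not an
  independent empirical estimate.  The recovered coefficients (0.0047,
  −0.0377, −0.1034) sit within 15% of the shipped reference betas, which is
  as close as a constructed tissue set can honestly claim.

The synthetic phantom (`phantom_spec()`/`generate_phantom()`) emulates a
scanned phantom: box regions of known materials on a voxel grid, noiseless
HU from the forward model, additive Gaussian HU noise with a single SD per
scan under a fixed seed (the minimal noise model — no texture, beam
hardening, partial volume or reconstruction artifacts).  Passing end-to-end
tests on it therefore demonstrates *self-consistency* of the
calibrate-and-convert pipeline (exact recovery in the noiseless case,
3-standard-error recovery with noise), not robustness to real scanner
physics.  Default test problem sizes — 10–20 voxels per axis, 5–8 materials,
1000-voxel ROIs, 1000 Monte-Carlo composition draws — were chosen as the
smallest sizes at which the statistical assertions (ROI standard-error
bounds, sub-0.7% soft-tissue error spread) are stable.

`sample_tissue_compositions()` models natural composition variability as
independent multiplicative jitter, $\omega_i(1 + v\,u_i)$ with
$u_i \sim U(-1,1)$, renormalized onto the simplex; components absent from
the base stay absent.  With $v = 0.1$ — the upper end of reported
soft-tissue variation — converting muscle-like draws with the nominal
composition stays within 0.7% on ρ_e.

## Numerical choices and degenerate inputs

* **Rounding.**  Internal computation is never rounded.  Comparisons with
  printed tables use `round_half_away()` (half away from zero), matching
  how such tables are displayed; R's own `round()` rounds half to even.
* **Air.**  `HU = -1000` maps to ρ = 0 exactly.  Below −1000, scalar calls
  raise (a scalar sub-air input is almost certainly a bug) while
  bulk/voxel calls (`bulk = TRUE`, `convert_volume()`) zero the voxel and
  log the count — real volumes contain air and noise excursions below it.
* **Composition sums.**  Hand-entered tables are often off in the last
  digit: deviations from unit sum up to 1e-3 are renormalized with a
  message; larger ones raise.  Percent-style tables (sums near 100) are
  detected and divided through.
* **Rank checks.**  Both regressions refuse rank-deficient designs (e.g.
  all-water material sets) with a diagnostic rather than returning an
  arbitrary pseudo-inverse solution.
* **LUT ties and extrapolation.**  Duplicate HU breakpoints are averaged
  (logged).  Beyond the calibrated range the terminal segments continue
  linearly — the clinical convention — with a warning once a query exceeds
  the range by more than 10% of its span.
* **Degenerate denominators.**  $\sum\omega\alpha + 1000 \le 0$ (possible
  only for nonphysical coefficient sets) raises before any division.

## Known limitations

* The model is only as good as the composition map supplied to it; mineral
  confusions cost 4–8% (see the sensitivity grid), so boney voxels need
  better composition priors than soft tissue.
* The bundled attenuation values are a transcribed XCOM-style compilation
  accurate to about 1%; spectrum-route alphas inherit that plus the
  spectrum-model uncertainty, which is why only the phantom route feeds the
  reference parameters.
* MV spectra are reduced to a two-parameter gamma shape; a measured
  spectrum should be preferred when available.
* One reference-table reproduction is knowingly imperfect: three of the
  nine MV $\mathrm{HU}_\rho$ cells of the calibration phantom table differ
  by one integer step when recomputed from the *printed* (rounded) HU and
  density, consistent with the original cells having been computed from
  unrounded measurements.  The corresponding test is left failing rather
  than loosened.
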