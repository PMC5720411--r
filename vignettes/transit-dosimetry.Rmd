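---
title: "Transit dosimetry for tangential breast fields: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transit dosimetry for tangential breast fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epidtransit)
```

## The problem

During tangential breast irradiation, the electronic portal imaging device
(EPID) mounted opposite the treatment beam records the radiation transmitted
through the patient at every session. Because the transit signal depends on
how much tissue the beam crossed, it can be inverted into an estimate of the
dose actually delivered at the breast midpoint — an *in vivo* dosimetry check
that requires no extra hardware or patient time. The catch is setup
variability: the breast contour is strongly curved, so a setup shift of a few
millimetres changes the tissue thickness crossed by the central axis, and a
naive inversion misattributes that change to a dose error. This package
implements the complete chain — calibration, ray tracing, dose
reconstruction, setup-shift correction by 1D profile alignment, and QA
reporting — together with a seeded simulator, so every step is testable
without clinical data.

## The calibrated transit model

**Correlation function.** For cylindrical water phantoms irradiated on their
lateral surface, the ratio of the EPID transit signal $S_t$ [CU] to the
midplane dose $D_m$ [Gy] depends, to very good approximation, only on the
chord thickness $w$ crossed by the central axis:

$$F(w) = a_1 w^2 + a_2 w + a_3 \quad [\mathrm{CU\,Gy^{-1}}].$$

The packaged default coefficients (`default_calibration()`) are
$a_1 = 5.819\times10^{-4}$, $a_2 = 2.880\times10^{-2}$,
$a_3 = 5.480\times10^{-1}$, measured at 6 MV with the imager at 150 cm from
the source; the measured ratios are independent of field size, wedge angle
(15° vs 30°) and phantom radius within ±0.5%, which is why a single pooled
quadratic serves and why `correlation_fit()` accepts but does not stratify by
wedge. Its supported interval defaults to $w \in [5, 29]$ cm, the range
spanned by the calibration phantom diameters; evaluation outside warns rather
than errors, since mild extrapolation is routine for small breasts.

**Scatter factor.** When the phantom midpoint sits a distance $d$ from the
isocenter along the beam (positive farther from the source), the scatter
reaching the imager changes. The correction is linear,

$$f(d, r) = f_0(r)\, d + 1,$$

with the slope tabulated at the four calibration radii
$r \in \{6.0, 8.3, 10.7, 14.5\}$ cm:
$f_0 = \{0.998, 1.487, 2.094, 2.756\}\times10^{-3}\ \mathrm{cm^{-1}}$.
`scatter_eval()` interpolates $f_0$ linearly in $r$ and clamps beyond the
table ends with a warning — clamping is the conservative choice given only
four support points. (The calibration literature quotes the second radius
both as 8.25 cm, the physical phantom, and 8.3 cm in the slope table; the
package uses 8.3 cm throughout.)

**Midpoint inversion.** The dose at the chord midpoint P follows from

$$D_m = S_t' \cdot \frac{f(d, r)}{F(w)} \cdot \left(\frac{SAD + d}{SAD}\right)^2,$$

implemented in `midpoint_dose()`. At $d = 0$ this is simply $S_t/F(w)$, and
the same function applies off axis (`offaxis_dose()`) because the fan lines
of a 100 cm SAD beam diverge so little over a breast-sized field that each
off-axis chord behaves like a central one.

## Profile reconstruction along the apex–lung segment

For a full dose profile, each sample of the transit profile defines a fan
line from the source through the imager pixel. The dose at the intersection
P0 of that fan line with the reconstruction segment $\overline{CD}$ (the line
through the central-axis chord midpoint P, perpendicular to the beam) is

$$D = S_{to}\, C, \qquad
C = \frac{f(d, r)}{F(w')} \left(\frac{SAD + d_1}{SAD}\right)^2
\left(\frac{SAD + d_1}{SAD + d_1 + d_2}\right)^2
e^{-(\mu_{en}/\rho)\, w_2'},$$

where $w'$ is the chord's *radiological* thickness (the line integral of
relative electron density — `radiological_path()`), P' is the point at half
radiological thickness, $d_1$ its offset from the isocenter plane, $d_2$ the
signed P'→P0 distance, and $w_2'$ the radiological thickness between P' and
P0 carrying the sign of $d_2$; $\mu_{en}/\rho = 2.73\times10^{-2}$
cm²·g⁻¹ is the water mass energy absorption coefficient at the 1.7 MeV
mean photon energy of a 6 MV beam (configurable via `physics_constants()`,
since published mean-energy estimates range up to 2.2 MeV).

**Sign conventions.** All longitudinal offsets are measured from the source
outward: $d, d_1 > 0$ farther from the source than the isocenter. For $d_2$
we adopt $d_2 = \mathrm{dist}(\mathrm{source}, P_0) -
\mathrm{dist}(\mathrm{source}, P')$, i.e. positive when the dose point lies
*beyond* P'. This is the only orientation under which the three defining
relations hold simultaneously: $d = d_1 + d_2$ on the central axis, the
second inverse-square ratio equals $(\mathrm{dist}\,P'/\mathrm{dist}\,P_0)^2$,
and the exponential *attenuates* the dose at points deeper along the ray.
Descriptions of this geometry elsewhere are internally inconsistent on the
orientation of $d_2$; we follow the formulas, not the prose.

**Scatter factor along the profile.** $f(d, r)$ is evaluated once for the
central-axis chord and held constant along $\overline{CD}$: the factor is
within a percent of unity over the calibrated $|d| \le 4$ cm, and its
variation across a profile is far below the other uncertainty sources.

**Equivalent radius.** For a patient slice, $r$ comes from the sagitta
construction: with $w$ the central chord and $\overline{CP}$ the distance
from the chord midpoint to the apex along the profile direction,
$r = (w^2 + 4\overline{CP}^2)/(8\overline{CP})$ (`sagitta_radius()`); the
apex is taken as the nearer body-contour crossing along the reconstruction
segment. A degenerate (flat) contour falls back to the largest tabulated
radius with a warning.

**Interface exclusion.** Within about 1 cm of a density interface (breast
contour, tissue/lung boundary) lateral electronic equilibrium fails and
neither the calibration nor a simple attenuation term is trustworthy, so
`profile_dose()` marks points within `exclusion_margin = 1` cm of an
interface as excluded rather than reporting a number. An interface is
detected where the relative density change between samples one grid cell
apart exceeds 0.2 — large enough to ignore interpolation ripple on a smooth
grid, small enough to catch the tissue/lung step (0.7 relative).

## Setup-shift correction

Clinically, portal images are aligned by eye against the planning DRR. The
package formalizes the part of that operation the dose reconstruction
actually consumes: a 1D match along the profile direction. The breast edge on
a transit profile is the position where the signal crosses 50% of the way
between the open-beam plateau (median of the top decile of samples) and the
minimum attenuated level, interpolated between grid samples and approached
from the plateau side (`breast_edge_position()`). The setup shift is then the
difference between the acquired and planned edge positions
(`estimate_shift()`), and the transit signal for the midpoint inversion is
read at the shifted projection of the midpoint — because the midpoint moved
with the patient. The 50%-edge criterion is our operationalization of the
operator's "profile coincidence" judgement; on simulated profiles it recovers
shifts in the clinical ±2 cm range to well within the ±2 mm accuracy quoted
for manual alignment. Cranio-caudal misalignment is outside the 2D slice
model and is recorded, when provided, but not corrected.

## Uncertainty budget and tolerance levels

`default_uncertainty_budget()` packages the nine 2 SD components of the
midpoint reconstruction (signal reproducibility 1.1%, F(w) fit 2.0%, f(d,r)
fits 0.5%, inverse-square approximation 1.0%, radiological thickness 1.0%,
Sterling equivalent square 1.0%, linac output 2.0%, EPID calibration
stability 2.0%, DPI/DRR alignment 2.0%). Their quadrature
(`budget_quadrature()`) computes to ≈4.5%, while the combined in vivo
uncertainty is conventionally quoted as 4.4%; the package reports both rather
than hard-coding either, and `tolerance_level(4.4, 3.0)` — folding in the 3%
TPS calculation uncertainty — reproduces the clinical ±5% tolerance on the
ratio $R = D_m / D_{m,TPS}$. `session_report()` summarizes a cohort of QA
records (mean R, SD, fraction within tolerance) and flags beyond-tolerance
sessions; `misalignment_stats()` splits observed shifts into systematic and
random components.

## The simulator and what it does (not) emulate

`forward_transit()` generates transit signals by inverting the calibrated
reconstruction relation per fan line ($S_{to} = D_{true}/C$), rather than by
simulating radiation transport. This is deliberate: round trips are then
exact at zero noise, so tests isolate geometry, alignment and noise effects
without conflating them with transport-model error. Consequences to keep in
mind:

- Passing round-trip tests validates the *internal consistency* of the
  chain, not the physical accuracy of the calibration itself — that rests on
  the measured tables.
- Signal noise is multiplicative Gaussian with SD equal to half the 0.5%
  (2 SD) EPID reproducibility; every draw is seedable and seeded runs are
  bit-identical.
- The open-beam plateau outside the body is a constant (default 1.3× the
  largest in-body signal) — a cosmetic level that guarantees a detectable
  edge; real open-field profiles carry horns and wedge gradients.
- The default profile span runs from just inside the chest-side contour to
  3 cm beyond the apex, mirroring the tangential field whose open margin
  lies beyond the apex while its other edge sits inside the chest; this is
  what makes the breast edge unambiguous.
- Wedge fluence is not modelled. The clinical observation that a misaligned
  *wedged* field shifts the filter shadow relative to the breast — the
  dominant term of real PTV underdosage under misalignment — needs a
  TPS-grade wedge model and is out of scope; the simulator reproduces only
  the directional contrast (alignment on vs off shrinks the spread of R).
- Breathing, organ motion and the scatter deficit of low-density lung are
  not modelled; reconstructed lung doses inherit the homogeneous-phantom
  calibration's limitations.

Phantoms: `make_cylinder_slice()` reproduces the four calibration cylinders
(binary density grid); `make_breast_slice()` is a three-level (air/lung/
tissue) half-disc-on-chest-wall slice whose defaults (apex radius 7 cm, disc
center 4 cm below the axis, chest depth 10 cm, lung density 0.3 inset 1 cm
from the chest wall) put the central-axis chord mid-slope on the breast
curvature — the regime where setup shifts actually perturb the naive
inversion — and the default 1.8 Gy midplane dose is the standard daily
fraction of a 50.4 Gy course.

## Numerical choices

- **Grids and rays.** Density grids are sampled bilinearly; rays are
  integrated midpoint-rule with step = spacing/2 (0.05 cm at the default
  0.1 cm grid). Path integrals converge to <0.1% under step refinement.
- **Contour localization.** The body threshold (0.05 relative density)
  decides which samples are in-body; the contour position itself is
  localized where the density crosses *half its interior value* one cell
  inward. The naive threshold crossing is biased outward by nearly half a
  cell on a sharp edge; the half-interior-level crossing is unbiased, which
  matters because the geometric chord w feeds F(w) at ~4%/cm sensitivity.
- **P′ localization.** The half-radiological-thickness point interpolates
  the cumulative density integral between ray samples.
- **Fit conventions.** `correlation_fit()` is an ordinary least-squares
  quadratic of St/Dm on w, requiring ≥3 distinct thicknesses (exact
  interpolation at 3); `scatter_fit()` fixes the intercept at 1 (the d = 0
  self-ratio is definitionally unity) and solves the one-parameter slope per
  radius. Residual spreads are recorded as 2 SD of percent residuals.
- **Problem sizes.** The packaged accuracy checks use 110 fan lines per
  cylinder case over radii {6, 8.3, 10.7, 14.5} cm and displacements
  |d| ≤ 4 cm, 40 correlation samples, and 9 displacement points per scatter
  radius — comfortably enough that sampling error in a 2 SD statistic is a
  few percent of its value.

## A worked check

```{r roundtrip}
calib <- default_calibration()
slice <- make_cylinder_slice(8.25, spacing = 0.1)
prof <- forward_transit(slice, calib = calib, noise_2sd = 0)
dp <- profile_dose(prof, slice, calib = calib)
ok <- !dp$excluded & !is.na(dp$dose)
range(dp$dose[ok])  # 1.8 Gy everywhere at zero noise
```

## Known limitations

The model is two-dimensional: everything lives in the isocenter slice, so
cranio-caudal anatomy changes, couch rotations and non-coplanar geometry are
invisible. Lung dose is reported but carries uncalibrated scatter error near
and inside low-density regions. The alignment is 1D edge matching — adequate
for the apex–lung direction the reconstruction consumes, not a substitute
for 2D image registration. And the simulator's fidelity is calibrational,
not transport-level: quantitative claims about real patients rest on the
measured calibration tables and the published uncertainty budget, not on the
synthetic phantoms.
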