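# epidtransit

In vivo transit dosimetry for tangential breast irradiation from EPID portal
images.

During breast radiotherapy, the portal imager (EPID) behind the patient
records the transmitted beam at every session. Because the transit signal
depends on the tissue thickness crossed, it can be inverted into the dose
actually delivered at the breast midpoint — a per-session QA check with no
extra hardware. The complication is patient setup: the breast contour is
strongly curved, so a shift of a few millimetres changes the chord crossed by
the beam axis and a naive inversion misreads it as a dose error. This package
implements the full chain, including the setup-shift correction:

- **Calibration** — the correlation function `F(w) = a1 w² + a2 w + a3`
  (transit signal per unit midplane dose versus chord thickness `w`) and the
  scatter factor `f(d, r) = f0(r) d + 1` for a phantom midpoint displaced by
  `d`, with the published 6 MV / aS500 tables packaged as defaults and
  fitting routines (`correlation_fit()`, `scatter_fit()`) for new data.
- **Geometry** — radiological path lengths through a 2D density slice,
  chord/fan-line construction, the sagitta-derived equivalent cylinder
  radius `r = (w² + 4·CP²)/(8·CP)`.
- **Reconstruction** — midpoint dose
  `Dm = St' · f(d,r)/F(w) · ((SAD+d)/SAD)²` and full dose profiles
  `D = Sto · C` along the apex–lung segment, with per-fan-line factors
  combining `F(w')`, inverse-square terms and an `exp(−μen/ρ · w2')`
  attenuation correction, and 1 cm interface exclusion.
- **Alignment** — 1D portal-profile / reference-edge matching that recovers
  the setup shift and reads the transit signal at the shifted midpoint
  projection.
- **QA** — quadrature uncertainty propagation into tolerance levels
  (`tolerance_level(4.4, 3.0)` → the clinical ±5% on `R = Dm/Dm,TPS`),
  per-cohort session reports, misalignment statistics.
- **Simulator** — seeded synthetic phantoms (the four calibration cylinders,
  a breast slice with a lung region), forward transit signals, noise and
  injected misalignments, so the whole chain is testable offline.

## Worked example

Simulate one therapy session in which the patient is set up 1.2 cm off the
planned position, then reconstruct the midpoint dose with and without the
alignment correction:

```r
library(epidtransit)

calib <- default_calibration()
slice <- make_breast_slice()                       # planning slice

planned <- forward_transit(slice, calib = calib, noise_2sd = 0)
ref_edge <- as.numeric(breast_edge_position(planned))   # DRR-like reference: 3.10 cm

session <- apply_misalignment(
  forward_transit(slice, calib = calib, noise_2sd = 0.5, seed = 42),
  shift_s = 1.2)                                   # the patient moved 1.2 cm

reconstruct_midpoint(session, slice, calib = calib,
                     align = TRUE, reference_edge = ref_edge)
#> <midpoint_result> Dm 1.800 Gy (St' 1.721 CU, shift +1.20 cm; w 11.50 cm, d +0.00 cm, r 6.91 cm)

reconstruct_midpoint(session, slice, calib = calib, align = FALSE)
#> <midpoint_result> Dm 1.896 Gy (St' 1.813 CU, shift +0.00 cm; w 11.50 cm, d +0.00 cm, r 6.91 cm)
```

The generating dose was 1.8 Gy (the standard daily fraction). With the
alignment correction the reconstruction recovers it exactly (R = 1.000,
estimated shift +1.20 cm); ignoring the shift reads the signal from the wrong
chord and overestimates the dose by 5.3% — beyond the ±5% clinical tolerance,
a false alarm the alignment step removes. `profile_dose()` extends the same
inversion to the whole apex–lung profile, and `session_report()` summarizes a
cohort of such checks.

A thin command-line wrapper over the same functions is installed at
`inst/cli/epidtransit` (subcommands `simulate`, `align`,
`reconstruct-midpoint`, `reconstruct-profile`, `qa-report`).

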