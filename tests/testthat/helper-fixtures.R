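# Shared fixtures, built once per test run. Coarser grids than the package
# defaults keep the suite fast; accuracy-sensitive tests build their own.

fix_calib <- default_calibration()
fix_beam <- beam_geometry()

fix_breast <- make_breast_slice(spacing = 0.15)
fix_breast_ref <- forward_transit(fix_breast, fix_beam, fix_calib, noise_2sd = 0)
fix_breast_edge <- as.numeric(breast_edge_position(fix_breast_ref))

fix_cyl <- make_cylinder_slice(8.25, spacing = 0.15)

# Quadratic evaluated the plain way, as an independent check on model code.
polyval2 <- function(a1, a2, a3, w) a1 * w^2 + a2 * w + a3
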