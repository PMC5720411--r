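# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream; `seed = NULL` uses the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Synthetic cylindrical water phantom slice
#'
#' A uniform water cylinder (relative density 1) of radius `r`, the geometry
#' of the calibration phantoms. The center can be displaced along the beam
#' axis to emulate a midpoint displacement `d`.
#'
#' @param r Cylinder radius \[cm\] (> 2 grid cells).
#' @param spacing Grid cell size \[cm\].
#' @param center Length-2 cylinder center \[cm\]; `center[1] = d` displaces
#'   the phantom along the beam.
#' @param margin Air margin \[cm\] around the cylinder.
#' @return A [phantom_slice()].
#' @export
make_cylinder_slice <- function(r, spacing = 0.1, center = c(0, 0), margin = 3) {
  if (r <= 0) stop("`r` must be positive")
  if (r < 2 * spacing) stop("`r` must exceed two grid cells")
  half <- r + margin
  n <- 2L * as.integer(ceiling(half / spacing)) + 1L
  origin <- center - spacing * (n - 1) / 2
  xs <- origin[1] + (seq_len(n) - 1) * spacing
  ys <- origin[2] + (seq_len(n) - 1) * spacing
  dx2 <- (xs - center[1])^2
  dy2 <- (ys - center[2])^2
  grid <- outer(dx2, dy2, `+`) <= r^2
  phantom_slice(grid + 0, spacing = spacing, origin = origin)
}

#' Synthetic breast-shaped slice with a lung region
#'
#' A three-level density map (air 0 / lung `lung_density` / tissue 1): a disc
#' of radius `apex_radius` (the breast, apex pointing away from the chest)
#' merged with a rectangular chest wall containing an embedded low-density
#' lung region inset by `lung_margin` from the chest-wall edges. With the
#' default placement the beam central axis (y = 0) crosses the breast disc
#' only, and the reconstruction segment runs from the apex through the breast
#' midpoint into the lung.
#'
#' @param apex_radius Breast disc radius \[cm\].
#' @param chest_depth Chest-wall depth \[cm\] below the disc center.
#' @param lung_density Relative density of the lung region in (0, 1).
#' @param spacing Grid cell size \[cm\].
#' @param breast_center Disc center \[cm\]; default `c(0, -4)` puts the apex
#'   at y = `apex_radius - 4` and the central-axis chord mid-slope on the
#'   breast curvature.
#' @param chest_halfwidth Chest-wall half-extent \[cm\] along the beam;
#'   default `apex_radius`.
#' @param lung_margin Tissue rind \[cm\] between chest-wall edge and lung.
#' @param margin Air margin \[cm\] around the body.
#' @return A [phantom_slice()].
#' @export
make_breast_slice <- function(apex_radius = 7, chest_depth = 10,
                              lung_density = 0.3, spacing = 0.1,
                              breast_center = c(0, -4),
                              chest_halfwidth = apex_radius,
                              lung_margin = 1, margin = 3) {
  if (apex_radius <= 0 || chest_depth <= 0 || chest_halfwidth <= 0) {
    stop("dimensions must be positive")
  }
  if (lung_density <= 0 || lung_density > 1) {
    stop("`lung_density` must be in (0, 1]")
  }
  if (2 * lung_margin >= min(2 * chest_halfwidth, chest_depth)) {
    stop("`lung_margin` leaves no room for the lung region")
  }
  cx <- breast_center[1]; cy <- breast_center[2]
  xlim <- c(cx - max(apex_radius, chest_halfwidth) - margin,
            cx + max(apex_radius, chest_halfwidth) + margin)
  ylim <- c(cy - chest_depth - margin, cy + apex_radius + margin)
  nx <- as.integer(ceiling(diff(xlim) / spacing)) + 1L
  ny <- as.integer(ceiling(diff(ylim) / spacing)) + 1L
  xs <- xlim[1] + (seq_len(nx) - 1) * spacing
  ys <- ylim[1] + (seq_len(ny) - 1) * spacing
  X <- matrix(xs, nx, ny)
  Y <- matrix(ys, nx, ny, byrow = TRUE)
  disc <- (X - cx)^2 + (Y - cy)^2 <= apex_radius^2
  chest <- abs(X - cx) <= chest_halfwidth & Y <= cy & Y >= cy - chest_depth
  lung <- abs(X - cx) <= chest_halfwidth - lung_margin &
    Y <= cy - lung_margin & Y >= cy - chest_depth + lung_margin
  grid <- matrix(0, nx, ny)
  grid[disc | chest] <- 1
  grid[lung] <- lung_density
  phantom_slice(grid, spacing = spacing, origin = c(xlim[1], ylim[1]))
}

#' Forward-simulate a transit profile
#'
#' Generates the transit signals a calibrated EPID would record for a known
#' dose distribution: per fan line, `Sto = D_true(P0) / C`, the exact
#' inversion of the reconstruction relation, so that reconstruction recovers
#' the generating dose identically at zero noise. Outside the body the signal
#' is the open-beam plateau. Multiplicative Gaussian noise with
#' SD = `noise_2sd / 2` percent models the EPID signal reproducibility.
#'
#' The forward model inverts the calibrated relation rather than simulating
#' radiation transport: round trips are exact by construction, which isolates
#' geometry, alignment and noise effects in downstream tests.
#'
#' @param slice A [phantom_slice()].
#' @param beam A [beam_geometry()].
#' @param calib An [epid_calibration()].
#' @param constants A [physics_constants()].
#' @param true_dose Midplane dose \[Gy\]: a scalar (constant along the
#'   profile) or a function of the coordinate along the reconstruction
#'   segment CD relative to the midpoint P.
#' @param positions Isocenter-plane sample positions \[cm\]; default a
#'   uniform grid of pitch `pitch` running from just inside the chest-side
#'   body contour to 3 cm beyond the apex (+y) side, emulating the tangential
#'   field whose open-beam margin lies beyond the breast apex while its other
#'   edge sits inside the chest.
#' @param pitch Default grid pitch \[cm\] at the isocenter plane.
#' @param noise_2sd Multiplicative noise, percent at 2 SD (0 disables).
#' @param seed Optional RNG seed for the noise draw (restores the caller's
#'   RNG state afterwards).
#' @param open_field_cu Open-beam plateau signal \[CU\]; default
#'   1.3 x the largest in-body signal, which guarantees a detectable breast
#'   edge for the alignment module.
#' @param step Ray sampling step \[cm\].
#' @return A [transit_profile()] with the generating geometry in `meta`.
#' @export
forward_transit <- function(slice, beam = beam_geometry(),
                            calib = default_calibration(),
                            constants = physics_constants(),
                            true_dose = 1.8, positions = NULL, pitch = 0.2,
                            noise_2sd = 0.5, seed = NULL,
                            open_field_cu = NULL, step = slice$spacing / 2) {
  geo <- central_axis_geometry(slice, beam, calib, step = step)
  if (is.null(geo)) stop("central axis does not cross the body")
  if (is.null(positions)) {
    occ <- which(slice$grid > slice$body_threshold, arr.ind = TRUE)
    yr <- slice$origin[2] + (range(occ[, 2]) - 1) * slice$spacing
    positions <- seq(yr[1] + 1, yr[2] + 3, by = pitch)
  }
  dose_fun <- if (is.function(true_dose)) true_dose else function(p) true_dose
  sad <- beam$sad
  f_central <- scatter_eval(calib$scatter, geo$chord$d, geo$r, warn = FALSE)
  n <- length(positions)
  sig <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    fanl <- fan_line(positions[i], beam)
    t_p0 <- (geo$x_p - fanl$source[1]) / fanl$dir[1]
    p0 <- as.numeric(fan_point(fanl, t_p0))
    ch <- chord_through(slice, fanl, beam, t_p0 = t_p0, step = step)
    if (!ch$in_body || density_at(slice, p0[1], p0[2]) <= slice$body_threshold) next
    Fw <- correlation_eval(calib$correlation, ch$w_prime, warn = FALSE)
    if (Fw <= 0) next
    C <- f_central / Fw * ((sad + ch$d1) / sad)^2 *
      ((sad + ch$d1) / (sad + ch$d1 + ch$d2))^2 *
      attenuation_factor(ch$w2_prime, constants)
    if (C <= 0) stop("non-positive dose reconstruction factor C")
    sig[i] <- dose_fun(p0[2] - geo$y_p) / C
  }
  if (all(is.na(sig))) stop("no fan line crosses the body")
  if (is.null(open_field_cu)) open_field_cu <- 1.3 * max(sig, na.rm = TRUE)
  sig[is.na(sig)] <- open_field_cu
  if (noise_2sd > 0) {
    sig <- with_seed(seed, sig * (1 + stats::rnorm(n, 0, noise_2sd / 200)))
  }
  transit_profile(positions, sig,
                  meta = list(true_dose = true_dose, noise_2sd = noise_2sd,
                              open_field_cu = open_field_cu,
                              d = geo$chord$d, r = geo$r, w = geo$chord$w))
}

#' Generate a synthetic calibration measurement set
#'
#' Emulates the two calibration campaigns on the cylindrical water phantoms:
#' correlation samples (`St/Dm` versus chord thickness `w` at `d = 0`) and
#' scatter samples (signals versus displacement `d` per radius, whose ratios
#' to the `d = 0` reference follow `f(d, r)`). Noise is multiplicative
#' Gaussian at half the quoted 2 SD; the `d = 0` scatter rows are the
#' noise-free definitional reference so that the ratio noise equals
#' `ratio_noise_2sd`.
#'
#' @param calib Generating [epid_calibration()].
#' @param radii Phantom radii \[cm\] for the scatter samples.
#' @param w_grid Chord thicknesses \[cm\] for the correlation samples;
#'   default `n_w` draws uniform on `w_range`.
#' @param n_w,w_range Size and support of the default `w` draw.
#' @param d_grid Displacements \[cm\] per radius (must include 0).
#' @param dm_gy Midplane dose \[Gy\] of the simulated irradiations.
#' @param noise_2sd Percent noise (2 SD) on the correlation signals.
#' @param ratio_noise_2sd Percent noise (2 SD) on the scatter ratios.
#' @param seed Optional RNG seed.
#' @return Data frame with columns `kind` ("correlation"/"scatter"), `w_cm`,
#'   `st_cu`, `dm_gy`, `wedge_deg`, `field_cm`, `r_cm`, `d_cm`, consumable by
#'   [correlation_fit()] and [scatter_fit()].
#' @export
generate_calibration_set <- function(calib = default_calibration(),
                                     radii = c(6, 8.3, 10.7, 14.5),
                                     w_grid = NULL, n_w = 40, w_range = c(5, 29),
                                     d_grid = -4:4, dm_gy = 1.8,
                                     noise_2sd = 0.5, ratio_noise_2sd = 0.2,
                                     seed = NULL) {
  if (!0 %in% d_grid) stop("`d_grid` must include the d = 0 reference")
  with_seed(seed, {
    if (is.null(w_grid)) w_grid <- sort(stats::runif(n_w, w_range[1], w_range[2]))
    nw <- length(w_grid)
    Fw <- correlation_eval(calib$correlation, w_grid, warn = FALSE)
    st <- Fw * dm_gy * (1 + stats::rnorm(nw, 0, noise_2sd / 200))
    corr <- data.frame(
      kind = "correlation", w_cm = w_grid, st_cu = st, dm_gy = dm_gy,
      wedge_deg = rep(c(15, 30), length.out = nw),
      field_cm = rep(seq(16, 24, by = 2), length.out = nw),
      r_cm = w_grid / 2, d_cm = 0, stringsAsFactors = FALSE)
    scat <- do.call(rbind, lapply(radii, function(r) {
      st0 <- correlation_eval(calib$correlation, 2 * r, warn = FALSE) * dm_gy
      f <- scatter_eval(calib$scatter, d_grid, r, warn = FALSE)
      eps <- ifelse(d_grid == 0, 0, stats::rnorm(length(d_grid), 0, ratio_noise_2sd / 200))
      data.frame(
        kind = "scatter", w_cm = 2 * r, st_cu = st0 / (f * (1 + eps)),
        dm_gy = dm_gy, wedge_deg = 15, field_cm = 20, r_cm = r, d_cm = d_grid,
        stringsAsFactors = FALSE)
    }))
    rbind(corr, scat)
  })
}

#' Apply a rigid setup misalignment to a transit profile
#'
#' Simulates the patient (not the EPID) moving by `shift_s` along the profile
#' direction: the signal support translates rigidly and is resampled onto the
#' original position grid with linear interpolation (constant extension at
#' the ends, where the profile sits on its plateaus).
#'
#' @param profile A [transit_profile()].
#' @param shift_s Patient shift \[cm\] at the isocenter plane.
#' @return A [transit_profile()] on the same grid.
#' @export
apply_misalignment <- function(profile, shift_s) {
  if (shift_s == 0) return(profile)
  s <- stats::approx(profile$positions + shift_s, profile$signals,
                     xout = profile$positions, rule = 2)$y
  transit_profile(profile$positions, s,
                  meta = c(profile$meta, list(applied_shift = shift_s)))
}

#' Simulate a cohort of therapy sessions
#'
#' Draws per-session setup shifts from a Gaussian with a systematic offset
#' and a random SD, forward-simulates the transit profile for each session
#' (fresh measurement noise), and applies the shift. The noiseless,
#' unshifted reference profile and its breast-edge position play the role of
#' the DRR-derived planning reference.
#'
#' @param slice Planning [phantom_slice()].
#' @param beam A [beam_geometry()].
#' @param calib An [epid_calibration()].
#' @param constants A [physics_constants()].
#' @param n Number of sessions (>= 1).
#' @param setup_sd_mm Random setup error SD \[mm\].
#' @param systematic_mm Systematic setup offset \[mm\].
#' @param noise_2sd Percent signal noise (2 SD) per session.
#' @param true_dose Generating midplane dose \[Gy\] (scalar or function).
#' @param seed Optional RNG seed.
#' @return An object of class `session_cohort`: `reference` (noise-free
#'   [transit_profile()]), `reference_edge` \[cm\], `dm_true` \[Gy\], and
#'   `sessions`, a list of `list(profile, true_shift_cm)`.
#' @export
simulate_cohort <- function(slice, beam = beam_geometry(),
                            calib = default_calibration(),
                            constants = physics_constants(), n = 20,
                            setup_sd_mm = 3.5, systematic_mm = 0,
                            noise_2sd = 0.5, true_dose = 1.8, seed = NULL) {
  stopifnot(n >= 1)
  reference <- forward_transit(slice, beam, calib, constants,
                               true_dose = true_dose, noise_2sd = 0)
  reference_edge <- as.numeric(breast_edge_position(reference))
  dm_true <- if (is.function(true_dose)) true_dose(0) else true_dose
  with_seed(seed, {
    shifts_cm <- stats::rnorm(n, systematic_mm, setup_sd_mm) / 10
    sessions <- lapply(seq_len(n), function(i) {
      noisy <- transit_profile(
        reference$positions,
        reference$signals * (1 + stats::rnorm(length(reference$signals),
                                              0, noise_2sd / 200)),
        meta = reference$meta)
      list(profile = apply_misalignment(noisy, shifts_cm[i]),
           true_shift_cm = shifts_cm[i])
    })
    structure(list(reference = reference, reference_edge = reference_edge,
                   dm_true = dm_true, sessions = sessions),
              class = "session_cohort")
  })
}

#' @export
print.session_cohort <- function(x, ...) {
  cat(sprintf("<session_cohort> %d sessions, reference edge %.2f cm, true Dm %.3f Gy\n",
              length(x$sessions), x$reference_edge, x$dm_true))
  invisible(x)
}

#' QA records for a simulated cohort
#'
#' Runs the midpoint reconstruction over every session of a
#' [simulate_cohort()] result, with or without the alignment correction, and
#' assembles the per-session QA records (the simulated truth stands in for
#' the TPS dose).
#'
#' @param cohort A `session_cohort`.
#' @param slice,beam,calib Geometry and calibration used for reconstruction.
#' @param align Apply the DPI/DRR alignment correction.
#' @return Data frame with columns `session`, `dm`, `dm_tps`, `ratio_r`,
#'   `shift_s`, `true_shift_cm`.
#' @export
cohort_records <- function(cohort, slice, beam = beam_geometry(),
                           calib = default_calibration(), align = TRUE) {
  stopifnot(inherits(cohort, "session_cohort"))
  rows <- lapply(seq_along(cohort$sessions), function(i) {
    s <- cohort$sessions[[i]]
    m <- reconstruct_midpoint(s$profile, slice, beam, calib, align = align,
                              reference_edge = cohort$reference_edge)
    data.frame(session = i, dm = m$dm, dm_tps = cohort$dm_true,
               ratio_r = ratio_r(m$dm, cohort$dm_true),
               shift_s = m$shift_s, true_shift_cm = s$true_shift_cm)
  })
  do.call(rbind, rows)
}
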