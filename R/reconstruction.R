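#' Physics constants for the attenuation correction
#'
#' @param mu_en_over_rho Water mass energy absorption coefficient
#'   \[cm^2 g^-1\] at the mean photon energy of the 6 MV beam (1.7 MeV);
#'   default 2.73e-2.
#' @return An object of class `physics_constants`.
#' @export
physics_constants <- function(mu_en_over_rho = 2.73e-2) {
  stopifnot(is.numeric(mu_en_over_rho), mu_en_over_rho > 0)
  structure(list(mu_en_over_rho = mu_en_over_rho), class = "physics_constants")
}

#' Transit signal profile at the isocenter plane
#'
#' A 1D profile of EPID transit signals resampled onto a uniform grid of
#' lateral positions expressed at the isocenter plane (EPID-plane positions
#' divided by SED/SAD).
#'
#' @param positions Strictly increasing lateral positions \[cm\].
#' @param signals Transit signals \[CU\], same length, non-negative (NA marks
#'   missing samples, e.g. after resampling outside the original support).
#' @param meta Optional named list of acquisition metadata (session id,
#'   monitor units, beam description, ...).
#' @return An object of class `transit_profile`.
#' @export
transit_profile <- function(positions, signals, meta = list()) {
  positions <- as.numeric(positions); signals <- as.numeric(signals)
  if (length(positions) != length(signals)) {
    stop("`positions` and `signals` must have the same length")
  }
  if (is.unsorted(positions, strictly = TRUE)) {
    stop("`positions` must be strictly increasing")
  }
  if (any(signals < 0, na.rm = TRUE)) stop("`signals` must be non-negative")
  structure(list(positions = positions, signals = signals, meta = meta),
            class = "transit_profile")
}

#' @export
print.transit_profile <- function(x, ...) {
  cat(sprintf("<transit_profile> %d samples on [%.2f, %.2f] cm (isocenter plane), signal [%.3f, %.3f] CU\n",
              length(x$positions), min(x$positions), max(x$positions),
              min(x$signals, na.rm = TRUE), max(x$signals, na.rm = TRUE)))
  invisible(x)
}

#' Midpoint dose from the transit signal
#'
#' Inverts the calibrated transit relation at the chord midpoint P:
#' `Dm = St' * f(d, r) / F(w) * ((SAD + d)/SAD)^2`,
#' where `St'` is the transit signal read at the projection of P on the EPID,
#' `w` the chord thickness, `d` the signed displacement of P from the
#' isocenter along the beam and `r` the equivalent cylinder radius.
#'
#' @param st_prime Transit signal \[CU\].
#' @param w Chord thickness \[cm\] along the beam central axis.
#' @param d Signed displacement \[cm\] of P from the isocenter.
#' @param r Equivalent cylinder radius \[cm\].
#' @param calib An [epid_calibration()].
#' @param beam A [beam_geometry()].
#' @param warn Forwarded to [correlation_eval()] / [scatter_eval()].
#' @return Midplane dose \[Gy\].
#' @export
midpoint_dose <- function(st_prime, w, d, r, calib = default_calibration(),
                          beam = beam_geometry(), warn = TRUE) {
  Fw <- correlation_eval(calib$correlation, w, warn = warn)
  if (any(Fw <= 0)) stop("F(w) <= 0: correlation model misuse")
  f <- scatter_eval(calib$scatter, d, r, warn = warn)
  st_prime * f / Fw * inverse_square(beam$sad, d)
}

#' Off-axis dose when the midpoint sits at the isocenter
#'
#' `D_Po = Sto / F(wo)`: with the chord midpoint at the isocenter the fan
#' lines are nearly parallel to the central axis, so the same correlation
#' function applies off axis with no displacement or scatter correction.
#'
#' @param sto Transit signal \[CU\] on the fan line.
#' @param wo Off-axis chord thickness \[cm\].
#' @inheritParams midpoint_dose
#' @return Dose \[Gy\] at the off-axis chord midpoint.
#' @export
offaxis_dose <- function(sto, wo, calib = default_calibration(), warn = TRUE) {
  Fw <- correlation_eval(calib$correlation, wo, warn = warn)
  if (any(Fw <= 0)) stop("F(w) <= 0: correlation model misuse")
  sto / Fw
}

#' Attenuation correction between P' and the dose point
#'
#' `exp(-mu_en/rho * w2')`, where `w2'` is the signed radiological thickness
#' from the half-thickness point P' to the dose point P0 (positive when P0 is
#' deeper, i.e. farther from the source).
#'
#' @param w2_signed Signed radiological thickness \[cm\].
#' @param constants A [physics_constants()].
#' @return Dimensionless factor.
#' @export
attenuation_factor <- function(w2_signed, constants = physics_constants()) {
  exp(-constants$mu_en_over_rho * w2_signed)
}

#' Dose reconstruction factor of a fan line
#'
#' The per-fan-line factor C converting the transit signal to dose at the
#' profile point P0:
#' `C = f(d, r)/F(w') * ((SAD + d1)/SAD)^2 * ((SAD + d1)/(SAD + d1 + d2))^2 *
#' exp(-mu_en/rho * w2')`,
#' with `w'` the chord radiological thickness, `d1` the offset of the half
#' radiological-thickness point P', `d2` the signed P'-to-P0 distance and
#' `w2'` the signed radiological thickness along it. `f(d, r)` uses the
#' central-axis chord's `d` and `r`, held constant along the profile. On the
#' central axis (`d2 = 0`, `w2' = 0`, `d1 = d`) the factor degenerates to the
#' midpoint relation.
#'
#' @param chord A [chord_through()] result carrying `w_prime`, `d1`, `d2`,
#'   `w2_prime`.
#' @param d,r Central-axis chord displacement \[cm\] and equivalent radius
#'   \[cm\] used in the scatter factor.
#' @param calib An [epid_calibration()].
#' @param constants A [physics_constants()].
#' @param beam A [beam_geometry()].
#' @param warn Forwarded to the calibration evaluators.
#' @return C \[Gy/CU\].
#' @export
fanline_c_factor <- function(chord, d, r, calib = default_calibration(),
                             constants = physics_constants(),
                             beam = beam_geometry(), warn = TRUE) {
  if (!isTRUE(chord$in_body) || chord$w_prime <= 0) {
    stop("fan line does not cross the body (w' <= 0)")
  }
  sad <- beam$sad
  d1 <- chord$d1
  d2 <- if (is.na(chord$d2)) 0 else chord$d2
  w2 <- if (is.na(chord$w2_prime)) 0 else chord$w2_prime
  if (sad + d1 + d2 <= 0) stop("SAD + d1 + d2 must be positive")
  Fw <- correlation_eval(calib$correlation, chord$w_prime, warn = warn)
  if (Fw <= 0) stop("F(w') <= 0: correlation model misuse")
  f <- scatter_eval(calib$scatter, d, r, warn = warn)
  f / Fw * ((sad + d1) / sad)^2 * ((sad + d1) / (sad + d1 + d2))^2 *
    attenuation_factor(w2, constants)
}

# Central-axis chord plus the sagitta-derived equivalent radius. The apex C is
# the nearer body-contour crossing along the reconstruction segment (the line
# through the chord midpoint P perpendicular to the beam axis); degenerate
# contours fall back to the largest tabulated radius with a warning.
central_axis_geometry <- function(slice, beam, calib, step = slice$spacing / 2) {
  chord <- chord_through(slice, fan_line(0, beam), beam, step = step)
  if (!chord$in_body) return(NULL)
  p <- chord$midpoint
  up <- contour_crossing(slice, p, c(0, 1), max_len = 100, step = step)
  dn <- contour_crossing(slice, p, c(0, -1), max_len = 100, step = step)
  cp <- suppressWarnings(min(up, dn, na.rm = TRUE))
  if (!is.finite(cp) || cp <= 0) {
    warning("degenerate contour: no apex found along the reconstruction segment; ",
            "using the largest tabulated radius")
    r <- max(calib$scatter$radii)
  } else {
    r <- sagitta_radius(chord$w, cp)
  }
  list(chord = chord, r = r, cp = cp, x_p = p[1], y_p = p[2])
}

#' Interface exclusion mask along a segment
#'
#' Flags positions lying within `margin` of a density interface along a
#' sampled segment. An interface is any pair of adjacent samples (one grid
#' cell apart) whose relative density change exceeds `rel_change`
#' (`|d2 - d1| / max(d1, d2)`); this catches both the body contour (air to
#' tissue) and internal steps such as the tissue/lung boundary. Dose points
#' near such interfaces are unreliable because lateral electronic equilibrium
#' breaks down there.
#'
#' @param slice A [phantom_slice()].
#' @param origin Length-2 point \[cm\] on the segment at coordinate 0.
#' @param direction Length-2 direction of the segment (normalized internally).
#' @param positions Signed coordinates \[cm\] along the segment to classify.
#' @param margin Exclusion half-width \[cm\] around each interface.
#' @param rel_change Relative density step defining an interface.
#' @return Logical vector: `TRUE` where the position is within `margin` of an
#'   interface.
#' @export
exclude_interfaces <- function(slice, origin, direction, positions,
                               margin = 1.0, rel_change = 0.2) {
  stopifnot(margin >= 0)
  u <- direction / sqrt(sum(direction^2))
  pad <- margin + 2 * slice$spacing
  lo <- min(positions) - pad; hi <- max(positions) + pad
  step <- slice$spacing
  ts <- seq(lo, hi, by = step)
  dens <- density_at(slice, origin[1] + ts * u[1], origin[2] + ts * u[2])
  a <- dens[-length(dens)]; b <- dens[-1]
  mx <- pmax(a, b)
  rel <- ifelse(mx > 0, abs(b - a) / mx, 0)
  iface <- which(rel > rel_change)
  if (length(iface) == 0) return(rep(FALSE, length(positions)))
  t_iface <- (ts[iface] + ts[iface + 1]) / 2
  vapply(positions, function(p) any(abs(p - t_iface) < margin + 1e-9), logical(1))
}

#' Reconstruct a dose profile from a transit profile
#'
#' For each transit-profile position, builds the fan line from the source,
#' intersects it with the reconstruction segment CD (the line through the
#' central-axis chord midpoint P, perpendicular to the beam axis), computes
#' the chord geometry and the per-fan-line factor C, and sets
#' `D = Sto * C`. The scatter factor `f(d, r)` uses the central-axis chord's
#' displacement and the sagitta-derived equivalent radius, held constant along
#' the profile. Points outside the body, and points within
#' `exclusion_margin` of a density interface along CD, are marked excluded.
#'
#' @param profile A [transit_profile()] (positions at the isocenter plane).
#' @param slice A [phantom_slice()].
#' @param beam A [beam_geometry()].
#' @param calib An [epid_calibration()].
#' @param constants A [physics_constants()].
#' @param exclusion_margin Interface exclusion half-width \[cm\] (default 1).
#' @param step Ray sampling step \[cm\]; default half the grid spacing.
#' @return A `dose_profile`: a data frame with columns `position` (coordinate
#'   of P0 along CD, cm), `dose` \[Gy\], `c_factor` \[Gy/CU\], `excluded`
#'   (logical) and `reason` (`""`, `"out-of-body"` or `"interface"`), with the
#'   central-axis geometry attached as attributes (`w`, `w_prime`, `d`, `r`).
#'   If no fan line crosses the body an empty profile is returned with a
#'   diagnostic attribute.
#' @export
profile_dose <- function(profile, slice, beam = beam_geometry(),
                         calib = default_calibration(),
                         constants = physics_constants(),
                         exclusion_margin = 1.0, step = slice$spacing / 2) {
  geo <- central_axis_geometry(slice, beam, calib, step = step)
  empty <- structure(
    data.frame(position = numeric(0), dose = numeric(0),
               c_factor = numeric(0), excluded = logical(0),
               reason = character(0), stringsAsFactors = FALSE),
    class = c("dose_profile", "data.frame"))
  if (is.null(geo)) {
    attr(empty, "diagnostic") <- "central axis does not cross the body"
    return(empty)
  }
  sad <- beam$sad
  d <- geo$chord$d
  r <- geo$r
  f_central <- scatter_eval(calib$scatter, d, r, warn = FALSE)
  x_p <- geo$x_p
  n <- length(profile$positions)
  pos_cd <- dose <- cfac <- rep(NA_real_, n)
  reason <- rep("", n)
  for (i in seq_len(n)) {
    fanl <- fan_line(profile$positions[i], beam)
    # P0: intersection of the fan line with the vertical segment x = x_p
    t_p0 <- (x_p - fanl$source[1]) / fanl$dir[1]
    p0 <- as.numeric(fan_point(fanl, t_p0))
    pos_cd[i] <- p0[2] - geo$y_p
    ch <- chord_through(slice, fanl, beam, t_p0 = t_p0, step = step)
    in_body <- ch$in_body && density_at(slice, p0[1], p0[2]) > slice$body_threshold
    if (!in_body || is.na(profile$signals[i])) {
      reason[i] <- "out-of-body"
      next
    }
    Fw <- correlation_eval(calib$correlation, ch$w_prime, warn = FALSE)
    if (Fw <= 0 || sad + ch$d1 + ch$d2 <= 0) {
      reason[i] <- "out-of-body"
      next
    }
    cfac[i] <- f_central / Fw * ((sad + ch$d1) / sad)^2 *
      ((sad + ch$d1) / (sad + ch$d1 + ch$d2))^2 *
      attenuation_factor(ch$w2_prime, constants)
    dose[i] <- profile$signals[i] * cfac[i]
  }
  near_iface <- exclude_interfaces(slice, origin = c(x_p, geo$y_p),
                                   direction = c(0, 1), positions = pos_cd,
                                   margin = exclusion_margin)
  iface <- near_iface & reason == ""
  reason[iface] <- "interface"
  out <- data.frame(position = pos_cd, dose = dose, c_factor = cfac,
                    excluded = reason != "", reason = reason,
                    stringsAsFactors = FALSE)
  structure(out, class = c("dose_profile", "data.frame"),
            w = geo$chord$w, w_prime = geo$chord$w_prime, d = d, r = r,
            cp = geo$cp)
}

#' @export
print.dose_profile <- function(x, ...) {
  ok <- !x$excluded & !is.na(x$dose)
  cat(sprintf("<dose_profile> %d points (%d reconstructed, %d excluded)\n",
              nrow(x), sum(ok), sum(x$excluded)))
  if (sum(ok)) {
    cat(sprintf("  dose range [%.3f, %.3f] Gy over [%.1f, %.1f] cm along CD\n",
                min(x$dose[ok]), max(x$dose[ok]),
                min(x$position[ok]), max(x$position[ok])))
  }
  if (!is.null(attr(x, "w"))) {
    cat(sprintf("  central axis: w %.2f cm, w' %.2f cm, d %+.2f cm, r %.2f cm\n",
                attr(x, "w"), attr(x, "w_prime"), attr(x, "d"), attr(x, "r")))
  }
  invisible(as.data.frame(x))
}

#' Midpoint dose from a session's transit profile
#'
#' The per-session clinical workflow: optionally estimate the setup shift by
#' aligning the acquired profile to the planned reference edge, read the
#' transit signal at the (shift-corrected) projection of the breast midpoint,
#' and invert the calibrated relation via [midpoint_dose()]. The chord
#' parameters (`w`, `d`, `r`) come from the planning slice.
#'
#' @param profile A [transit_profile()] acquired during the session.
#' @param slice The planning [phantom_slice()].
#' @param beam A [beam_geometry()].
#' @param calib An [epid_calibration()].
#' @param align If `TRUE`, estimate and correct the setup shift before
#'   sampling the signal.
#' @param reference_edge Planned breast-edge position \[cm\] (from the DRR or
#'   a reference forward profile); required when `align = TRUE`.
#' @param window A [sampling_window()] for the signal average.
#' @return A list of class `midpoint_result`: `dm` \[Gy\], `shift_s` \[cm\]
#'   (0 when `align = FALSE`), `st_prime` \[CU\], and the chord parameters
#'   `w`, `d`, `r`.
#' @export
reconstruct_midpoint <- function(profile, slice, beam = beam_geometry(),
                                 calib = default_calibration(), align = TRUE,
                                 reference_edge = NULL,
                                 window = sampling_window()) {
  geo <- central_axis_geometry(slice, beam, calib)
  if (is.null(geo)) stop("central axis does not cross the body")
  shift_s <- 0
  if (align) {
    if (is.null(reference_edge)) {
      stop("`reference_edge` is required when `align = TRUE`")
    }
    shift_s <- estimate_shift(profile, reference_edge)$shift_s
  }
  # the midpoint projection follows the patient: sample at 0 + shift
  st_prime <- sample_window_mean(profile, center = shift_s, window = window)
  dm <- midpoint_dose(st_prime, w = geo$chord$w, d = geo$chord$d, r = geo$r,
                      calib = calib, beam = beam, warn = FALSE)
  structure(list(dm = dm, shift_s = shift_s, st_prime = st_prime,
                 w = geo$chord$w, d = geo$chord$d, r = geo$r),
            class = "midpoint_result")
}

#' @export
print.midpoint_result <- function(x, ...) {
  cat(sprintf("<midpoint_result> Dm %.3f Gy (St' %.3f CU, shift %+.2f cm; w %.2f cm, d %+.2f cm, r %.2f cm)\n",
              x$dm, x$st_prime, x$shift_s, x$w, x$d, x$r))
  invisible(x)
}
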