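#' Beam geometry for a tangential field
#'
#' Describes the irradiation geometry of a single 6 MV tangential field in the
#' 2D slice model: the source sits at a distance `sad` from the isocenter along
#' the beam axis and the portal imager plane at `sed` from the source. All
#' lengths are in centimetres.
#'
#' The slice coordinate frame places the isocenter at the origin with the beam
#' travelling along +x (gantry at 90 degrees, lateral irradiation); y is the
#' lateral (profile) direction. Isocenter-plane lateral coordinates scale to
#' the EPID plane by `sed/sad` (similar triangles).
#'
#' @param sad Source-to-axis distance \[cm\].
#' @param sed Source-to-EPID distance \[cm\]; must exceed `sad`.
#' @param field_length Field extent along the phantom/patient axis \[cm\].
#' @param field_width Field extent along the profile direction \[cm\].
#' @param wedge_angle Hard wedge angle in degrees; one of 0, 15, 30.
#' @param gantry Gantry angle in degrees (90 for the lateral phantom setup).
#' @return An object of class `beam_geometry`.
#' @examples
#' beam_geometry()
#' @export
beam_geometry <- function(sad = 100, sed = 150, field_length = 20,
                          field_width = 10, wedge_angle = 0, gantry = 90) {
  stopifnot(is.numeric(sad), length(sad) == 1, is.numeric(sed), length(sed) == 1)
  if (sad <= 0) stop("`sad` must be positive")
  if (sed <= sad) stop("`sed` must exceed `sad`")
  if (!wedge_angle %in% c(0, 15, 30)) {
    stop("`wedge_angle` must be one of 0, 15, 30 degrees")
  }
  structure(
    list(sad = sad, sed = sed, field_length = field_length,
         field_width = field_width, wedge_angle = wedge_angle, gantry = gantry),
    class = "beam_geometry"
  )
}

#' @export
print.beam_geometry <- function(x, ...) {
  cat(sprintf("<beam_geometry> SAD %.1f cm, SED %.1f cm, field %.0f x %.0f cm, wedge %d deg\n",
              x$sad, x$sed, x$field_length, x$field_width, as.integer(x$wedge_angle)))
  invisible(x)
}

#' 2D relative electron density slice
#'
#' A rectangular grid of relative electron density (water = 1, air = 0) in the
#' isocenter slice plane. `grid[i, j]` covers the point
#' `x = origin[1] + (i-1)*spacing`, `y = origin[2] + (j-1)*spacing`
#' (cell centers; rows index x along the beam, columns index y across it).
#'
#' @param grid Numeric matrix of relative electron densities (all `>= 0`).
#' @param spacing Cell size \[cm\], equal in both directions.
#' @param origin Length-2 numeric: coordinates \[cm\] of the center of cell
#'   `[1, 1]`, isocenter at the origin.
#' @param body_threshold Density separating air from tissue; the body contour
#'   is taken where interpolated density crosses this value.
#' @return An object of class `phantom_slice`.
#' @seealso [make_cylinder_slice()], [make_breast_slice()], [read_phantom_slice()]
#' @export
phantom_slice <- function(grid, spacing, origin = NULL, body_threshold = 0.05) {
  grid <- as.matrix(grid)
  if (!is.numeric(grid)) stop("`grid` must be numeric")
  if (any(!is.finite(grid)) || any(grid < 0)) {
    stop("densities must be finite and >= 0")
  }
  if (!is.numeric(spacing) || length(spacing) != 1 || spacing <= 0) {
    stop("`spacing` must be a single positive number")
  }
  if (is.null(origin)) {
    # center the grid on the isocenter
    origin <- -spacing * (dim(grid) - 1) / 2
  }
  stopifnot(length(origin) == 2)
  structure(
    list(grid = grid, spacing = spacing, origin = as.numeric(origin),
         body_threshold = body_threshold),
    class = "phantom_slice"
  )
}

#' @export
print.phantom_slice <- function(x, ...) {
  cat(sprintf("<phantom_slice> %d x %d cells, spacing %.3f cm, origin (%.2f, %.2f) cm\n",
              nrow(x$grid), ncol(x$grid), x$spacing, x$origin[1], x$origin[2]))
  cat(sprintf("  density range [%.2f, %.2f], body threshold %.2f\n",
              min(x$grid), max(x$grid), x$body_threshold))
  invisible(x)
}

#' Relative electron density at arbitrary points
#'
#' Bilinear interpolation of the slice grid; points outside the grid return 0
#' (air). Vectorized over `x`, `y`.
#'
#' @param slice A [phantom_slice()].
#' @param x,y Coordinates \[cm\].
#' @return Numeric vector of densities.
#' @export
density_at <- function(slice, x, y) {
  g <- slice$grid
  sp <- slice$spacing
  fi <- (x - slice$origin[1]) / sp + 1
  fj <- (y - slice$origin[2]) / sp + 1
  i0 <- floor(fi); j0 <- floor(fj)
  ti <- fi - i0; tj <- fj - j0
  nr <- nrow(g); nc <- ncol(g)
  val <- function(i, j) {
    ok <- i >= 1 & i <= nr & j >= 1 & j <= nc
    out <- numeric(length(i))
    out[ok] <- g[cbind(i[ok], j[ok])]
    out
  }
  v00 <- val(i0, j0); v10 <- val(i0 + 1L, j0)
  v01 <- val(i0, j0 + 1L); v11 <- val(i0 + 1L, j0 + 1L)
  (1 - ti) * (1 - tj) * v00 + ti * (1 - tj) * v10 +
    (1 - ti) * tj * v01 + ti * tj * v11
}

#' Equivalent cylinder radius from chord and sagitta
#'
#' Radius of the circle through the endpoints of a chord of length `w` whose
#' apex rises `cp` above the chord midpoint (the sagitta construction used to
#' assign an equivalent cylindrical phantom to a breast contour):
#' `r = (w^2 + 4 cp^2) / (8 cp)`.
#'
#' @param w Chord length \[cm\], positive.
#' @param cp Sagitta \[cm\]: distance from the chord midpoint to the arc apex,
#'   positive.
#' @return Radius \[cm\].
#' @examples
#' sagitta_radius(12, 6)  # a diameter chord: recovers the radius 6
#' @export
sagitta_radius <- function(w, cp) {
  if (any(w <= 0) || any(cp <= 0)) stop("`w` and `cp` must be positive")
  (w^2 + 4 * cp^2) / (8 * cp)
}

#' Project between the isocenter plane and the EPID plane
#'
#' Lateral coordinates on the two planes are related by similar triangles
#' through the source: `epid = iso * sed/sad`.
#'
#' @param iso_coord,epid_coord Lateral position \[cm\].
#' @param beam A [beam_geometry()].
#' @return Projected lateral position \[cm\].
#' @export
project_iso_to_epid <- function(iso_coord, beam = beam_geometry()) {
  iso_coord * beam$sed / beam$sad
}

#' @rdname project_iso_to_epid
#' @export
project_epid_to_iso <- function(epid_coord, beam = beam_geometry()) {
  epid_coord * beam$sad / beam$sed
}

#' Inverse-square factor
#'
#' `((sad + d)/sad)^2`, the fluence correction for a point displaced by `d`
#' along the beam from the isocenter (d > 0 farther from the source).
#'
#' @param sad Source-to-axis distance \[cm\].
#' @param d Signed displacement \[cm\].
#' @return Dimensionless factor.
#' @export
inverse_square <- function(sad, d) {
  if (any(sad + d <= 0)) stop("`sad + d` must be positive")
  ((sad + d) / sad)^2
}

#' Sterling equivalent square
#'
#' Side of the square field equivalent to an `a` x `b` rectangle,
#' `2ab/(a + b)` (4 Area / Perimeter).
#'
#' @param a,b Rectangular field sides \[cm\], positive.
#' @return Equivalent square side \[cm\].
#' @export
sterling_equivalent_square <- function(a, b) {
  if (any(a <= 0) || any(b <= 0)) stop("field sides must be positive")
  2 * a * b / (a + b)
}

#' Fan line through an isocenter-plane point
#'
#' The ray from the source through a lateral position on the isocenter plane,
#' extended to the EPID plane. Positions along the ray are parametrized by the
#' distance `t` from the source, so the isocenter plane is at `t = sad` on the
#' central axis.
#'
#' @param iso_coord Lateral position \[cm\] on the isocenter plane.
#' @param beam A [beam_geometry()].
#' @return An object of class `fan_line` with the source point, unit direction,
#'   and the matching `iso_coord` / `epid_coord` pair.
#' @export
fan_line <- function(iso_coord, beam = beam_geometry()) {
  source <- c(-beam$sad, 0)
  target <- c(0, iso_coord)
  v <- target - source
  len <- sqrt(sum(v^2))
  structure(
    list(source = source, dir = v / len, iso_coord = iso_coord,
         epid_coord = iso_coord * beam$sed / beam$sad, t_iso = len),
    class = "fan_line"
  )
}

# Point on a fan line at distance t from the source.
fan_point <- function(fan, t) {
  cbind(fan$source[1] + t * fan$dir[1], fan$source[2] + t * fan$dir[2])
}

# Clip the ray t-range to the slice bounding box (with a half-cell margin).
ray_grid_range <- function(slice, fan) {
  sp <- slice$spacing
  lo <- slice$origin - sp / 2
  hi <- slice$origin + sp * (dim(slice$grid) - 0.5)
  tmin <- 0; tmax <- Inf
  for (k in 1:2) {
    o <- fan$source[k]; u <- fan$dir[k]
    if (abs(u) < 1e-12) {
      if (o < lo[k] || o > hi[k]) return(NULL)
    } else {
      t1 <- (lo[k] - o) / u; t2 <- (hi[k] - o) / u
      tmin <- max(tmin, min(t1, t2))
      tmax <- min(tmax, max(t1, t2))
    }
  }
  if (tmin >= tmax) return(NULL)
  c(tmin, tmax)
}

#' Radiological path length along a segment
#'
#' Water-equivalent length of the segment from `p0` to `p1`: the line integral
#' of relative electron density, evaluated by midpoint-rule sampling of the
#' bilinearly interpolated grid.
#'
#' @param slice A [phantom_slice()].
#' @param p0,p1 Length-2 numeric endpoints \[cm\].
#' @param step Sampling step \[cm\]; default half the grid spacing.
#' @return Water-equivalent length \[cm\]; 0 for a degenerate segment or a
#'   segment entirely in air.
#' @export
radiological_path <- function(slice, p0, p1, step = slice$spacing / 2) {
  stopifnot(step > 0)
  v <- p1 - p0
  len <- sqrt(sum(v^2))
  if (len == 0) return(0)
  n <- max(1L, ceiling(len / step))
  tm <- (seq_len(n) - 0.5) / n * len
  u <- v / len
  dens <- density_at(slice, p0[1] + tm * u[1], p0[2] + tm * u[2])
  sum(dens) * len / n
}

# Linear interpolation of the t at which sampled values cross `level`
# between samples k and k+1.
cross_t <- function(ts, vals, k, level) {
  dv <- vals[k + 1] - vals[k]
  if (dv == 0) return(ts[k])
  ts[k] + (level - vals[k]) / dv * (ts[k + 1] - ts[k])
}

# Contour localization at an entry (rising) or exit (falling) edge around the
# first/last in-body sample `k`: crossing of half the interior density one
# cell inward, searched over the samples spanning the edge ramp; falls back
# to the threshold crossing at the bracketing pair.
edge_cross <- function(ts, vals, k, thr, spacing, rising = TRUE) {
  n <- length(ts)
  stp <- ts[2] - ts[1]
  m <- max(1L, ceiling(spacing / stp))
  kin <- if (rising) min(n, k + m) else max(1L, k - m)
  level <- max(thr, vals[kin] / 2)
  win <- if (rising) max(1L, k - m - 1L):min(n - 1L, k + m) else
    max(1L, k - m):min(n - 1L, k + m + 1L)
  for (j in win) {
    lo <- min(vals[j], vals[j + 1]); hi <- max(vals[j], vals[j + 1])
    crosses <- lo < level && level <= hi
    dir_ok <- if (rising) vals[j + 1] >= vals[j] else vals[j + 1] <= vals[j]
    if (crosses && dir_ok) return(cross_t(ts, vals, j, level))
  }
  if (rising) cross_t(ts, vals, k - 1L, thr) else cross_t(ts, vals, k, thr)
}

#' Chord geometry along a fan line
#'
#' Traces a fan line through the slice: the body entry/exit points (density
#' crossing `body_threshold`, localized by linear interpolation), the geometric
#' chord length `w`, the radiological thickness `w_prime`, the half
#' radiological-thickness point P' and its signed offset `d1` from the SAD
#' line, and the chord midpoint offset `d`. If a target point P0 is supplied
#' (as its distance `t_p0` from the source along this fan line), the signed
#' distance `d2` from P' to P0 and the signed radiological thickness
#' `w2_prime` along it are also computed.
#'
#' Sign conventions: `d`, `d1` are positive when the point is farther from the
#' source than the isocenter plane; `d2` is positive when P0 is farther from
#' the source than P' (so that `d = d1 + d2` on the central axis, neglecting
#' divergence), and `w2_prime` carries the sign of `d2`.
#'
#' @param slice A [phantom_slice()].
#' @param fan A [fan_line()] (or an isocenter-plane lateral coordinate, which
#'   is promoted via [fan_line()]).
#' @param beam A [beam_geometry()].
#' @param t_p0 Optional distance \[cm\] from the source to the target point P0
#'   along the fan line.
#' @param step Ray sampling step \[cm\]; default half the grid spacing.
#' @return An object of class `chord_geometry`: a list with `in_body`, `w`,
#'   `w_prime`, `d`, `d1`, `d2`, `w2_prime`, `t_entry`, `t_exit`, `t_pprime`,
#'   `midpoint` (coordinates of the chord midpoint) and the generating
#'   `iso_coord`. Fan lines that miss the body return `in_body = FALSE` rather
#'   than an error.
#' @export
chord_through <- function(slice, fan, beam = beam_geometry(), t_p0 = NULL,
                          step = slice$spacing / 2) {
  if (is.numeric(fan)) fan <- fan_line(fan, beam)
  outside <- structure(
    list(in_body = FALSE, w = 0, w_prime = 0, d = NA_real_, d1 = NA_real_,
         d2 = NA_real_, w2_prime = NA_real_, t_entry = NA_real_,
         t_exit = NA_real_, t_pprime = NA_real_, midpoint = c(NA_real_, NA_real_),
         iso_coord = fan$iso_coord),
    class = "chord_geometry")
  rng <- ray_grid_range(slice, fan)
  if (is.null(rng)) return(outside)
  n <- max(2L, ceiling((rng[2] - rng[1]) / step))
  ts <- seq(rng[1], rng[2], length.out = n + 1L)
  pts <- fan_point(fan, ts)
  dens <- density_at(slice, pts[, 1], pts[, 2])
  thr <- slice$body_threshold
  inb <- dens > thr
  if (!any(inb)) return(outside)
  k1 <- which(inb)[1]
  k2 <- which(inb)[sum(inb)]
  # The threshold decides which samples are in-body; the contour itself is
  # localized where the density crosses half its interior value (sampled one
  # cell inward), which is unbiased for a sharp edge smeared over one cell by
  # the bilinear interpolation.
  t_entry <- if (k1 == 1L) ts[1] else {
    edge_cross(ts, dens, k1, thr, slice$spacing, rising = TRUE)
  }
  t_exit <- if (k2 == n + 1L) ts[n + 1L] else {
    edge_cross(ts, dens, k2, thr, slice$spacing, rising = FALSE)
  }
  w <- t_exit - t_entry
  if (w <= 0) return(outside)
  # radiological thickness and the half-thickness point P'
  m <- max(2L, ceiling(w / step))
  tm <- t_entry + (seq_len(m) - 0.5) / m * w
  pm <- fan_point(fan, tm)
  dm <- density_at(slice, pm[, 1], pm[, 2])
  dl <- w / m
  w_prime <- sum(dm) * dl
  cum <- cumsum(dm) * dl
  half <- w_prime / 2
  kk <- which(cum >= half)[1]
  if (is.na(kk)) {
    t_pprime <- (t_entry + t_exit) / 2
  } else if (kk == 1L) {
    t_pprime <- t_entry + (half / max(cum[1], .Machine$double.eps)) * dl
  } else {
    frac <- (half - cum[kk - 1L]) / max(cum[kk] - cum[kk - 1L], .Machine$double.eps)
    t_pprime <- t_entry + (kk - 1L + frac) * dl
  }
  sad <- beam$sad
  t_mid <- (t_entry + t_exit) / 2
  out <- outside
  out$in_body <- TRUE
  out$w <- w
  out$w_prime <- w_prime
  out$d <- t_mid - sad
  out$d1 <- t_pprime - sad
  out$t_entry <- t_entry
  out$t_exit <- t_exit
  out$t_pprime <- t_pprime
  out$midpoint <- as.numeric(fan_point(fan, t_mid))
  if (!is.null(t_p0)) {
    d2 <- t_p0 - t_pprime
    w2 <- radiological_path(slice, as.numeric(fan_point(fan, t_pprime)),
                            as.numeric(fan_point(fan, t_p0)), step = step)
    out$d2 <- d2
    out$w2_prime <- sign(d2) * w2
  }
  out
}

#' @export
print.chord_geometry <- function(x, ...) {
  if (!x$in_body) {
    cat(sprintf("<chord_geometry> iso %.2f cm: outside the body\n", x$iso_coord))
  } else {
    cat(sprintf(
      "<chord_geometry> iso %+.2f cm: w %.2f cm, w' %.2f cm, d %+.2f, d1 %+.2f%s\n",
      x$iso_coord, x$w, x$w_prime, x$d, x$d1,
      if (is.na(x$d2)) "" else sprintf(", d2 %+.2f, w2' %+.2f", x$d2, x$w2_prime)))
  }
  invisible(x)
}

# First body-contour crossing walking from `start` along unit `dir`
# (used to locate the apex C on the reconstruction segment). Returns the
# distance to the crossing, or NA if none within `max_len`.
contour_crossing <- function(slice, start, dir, max_len, step = slice$spacing / 2) {
  n <- max(2L, ceiling(max_len / step))
  ts <- seq(0, max_len, length.out = n + 1L)
  dens <- density_at(slice, start[1] + ts * dir[1], start[2] + ts * dir[2])
  thr <- slice$body_threshold
  inb <- dens > thr
  if (!inb[1]) return(NA_real_)
  k <- which(!inb)[1]
  if (is.na(k)) return(NA_real_)
  cross_t(ts, dens, k - 1L, max(thr, (dens[k - 1L] + dens[k]) / 2))
}
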