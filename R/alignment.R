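#' Signal sampling window
#'
#' The transit signal at a point is read as the mean over a small window of
#' EPID pixels centered on it: 5 x 5 = 25 pixels for 2D images, 5 samples for
#' 1D profiles.
#'
#' @param half_width Window half-width in pixels (default 2, i.e. 5 samples
#'   across).
#' @param pixel_pitch EPID pixel pitch \[cm\] at the detector plane.
#' @return An object of class `sampling_window`.
#' @export
sampling_window <- function(half_width = 2L, pixel_pitch = 0.0784) {
  stopifnot(half_width >= 0)
  structure(list(half_width = as.integer(half_width), pixel_pitch = pixel_pitch),
            class = "sampling_window")
}

#' Windowed mean of a profile or image
#'
#' Arithmetic mean over the sampling window centered on `center`: the
#' `2*half_width + 1` nearest samples of a 1D [transit_profile()], or the
#' square pixel block of a 2D matrix (with `center` a length-2 index pair).
#' Windows extending beyond the support are clipped with a warning.
#'
#' @param x A [transit_profile()], a numeric vector, or a numeric matrix.
#' @param center Window center: a position \[cm\] for a profile, an index for
#'   a vector, or a length-2 index pair for a matrix.
#' @param window A [sampling_window()].
#' @return Mean signal \[CU\].
#' @export
sample_window_mean <- function(x, center, window = sampling_window()) {
  hw <- window$half_width
  if (inherits(x, "transit_profile")) {
    ok <- which(!is.na(x$signals))
    if (length(ok) == 0) stop("profile has no valid samples")
    k <- ok[which.min(abs(x$positions[ok] - center))]
    idx <- (k - hw):(k + hw)
    if (any(idx < 1 | idx > length(x$signals))) {
      warning("sampling window clipped at the profile boundary")
      idx <- idx[idx >= 1 & idx <= length(x$signals)]
    }
    return(mean(x$signals[idx], na.rm = TRUE))
  }
  if (is.matrix(x)) {
    stopifnot(length(center) == 2)
    i <- round(center[1]); j <- round(center[2])
    ri <- (i - hw):(i + hw); rj <- (j - hw):(j + hw)
    if (any(ri < 1 | ri > nrow(x)) || any(rj < 1 | rj > ncol(x))) {
      warning("sampling window clipped at the image boundary")
      ri <- ri[ri >= 1 & ri <= nrow(x)]
      rj <- rj[rj >= 1 & rj <= ncol(x)]
    }
    if (length(ri) == 0 || length(rj) == 0) stop("empty sampling support")
    return(mean(x[ri, rj]))
  }
  # numeric vector with an index center
  k <- round(center)
  idx <- (k - hw):(k + hw)
  if (any(idx < 1 | idx > length(x))) {
    warning("sampling window clipped at the boundary")
    idx <- idx[idx >= 1 & idx <= length(x)]
  }
  if (length(idx) == 0) stop("empty sampling support")
  mean(x[idx])
}

#' Breast edge position on a transit profile
#'
#' Locates the body contour on a transit profile as the position where the
#' signal crosses 50% of the way between the open-beam plateau (median of the
#' top decile of samples) and the minimum attenuated level, walking inward
#' from the plateau side and interpolating linearly between grid samples.
#'
#' @param profile A [transit_profile()] containing both an open-beam plateau
#'   and an attenuated region.
#' @return Edge position \[cm\] at the isocenter plane, with attributes
#'   `plateau`, `floor` and `threshold` \[CU\].
#' @export
breast_edge_position <- function(profile) {
  s <- profile$signals
  p <- profile$positions
  ok <- !is.na(s)
  s <- s[ok]; p <- p[ok]
  if (length(s) < 4) stop("no edge: too few samples")
  plateau <- stats::median(s[s >= stats::quantile(s, 0.9)])
  floor_ <- min(s)
  if (plateau - floor_ <= max(1e-12, 1e-3 * plateau)) {
    stop("no edge: profile is flat")
  }
  thr <- floor_ + 0.5 * (plateau - floor_)
  # walk inward from the end with the higher outer-decile mean
  n <- length(s)
  k <- max(2L, ceiling(n / 10))
  from_left <- mean(s[seq_len(k)]) >= mean(s[(n - k + 1):n])
  if (!from_left) { s <- rev(s); p <- rev(p) }
  above <- s >= thr
  if (!above[1]) stop("no edge: plateau end is below the 50% level")
  j <- which(!above)[1]
  if (is.na(j)) stop("no edge: signal never drops below the 50% level")
  frac <- (thr - s[j - 1]) / (s[j] - s[j - 1])
  edge <- p[j - 1] + frac * (p[j] - p[j - 1])
  structure(edge, plateau = plateau, floor = floor_, threshold = thr)
}

#' Estimate the patient setup shift from a portal profile
#'
#' The shift `s` along the profile direction is the displacement of the
#' acquired (DPI) breast edge from the planned reference edge (from the DRR):
#' `s = edge(dpi) - reference_edge`, both at the isocenter plane. The
#' confidence score is an edge-contrast heuristic in \[0, 1\].
#'
#' @param dpi A [transit_profile()] acquired during the session.
#' @param reference_edge Planned edge position \[cm\] at the isocenter plane.
#' @return An object of class `alignment_result`: `shift_s` \[cm\],
#'   `edge_dpi`, `edge_ref` and `confidence`.
#' @export
estimate_shift <- function(dpi, reference_edge) {
  edge <- breast_edge_position(dpi)
  plateau <- attr(edge, "plateau"); floor_ <- attr(edge, "floor")
  contrast <- (plateau - floor_) / max(plateau, .Machine$double.eps)
  structure(
    list(shift_s = as.numeric(edge) - reference_edge,
         edge_dpi = as.numeric(edge), edge_ref = reference_edge,
         confidence = max(0, min(1, contrast))),
    class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> shift %+.2f cm (edge %.2f vs reference %.2f cm, confidence %.2f)\n",
              x$shift_s, x$edge_dpi, x$edge_ref, x$confidence))
  invisible(x)
}

#' Resample a profile onto its grid after undoing a setup shift
#'
#' Translates the profile by `-shift_s` (so an estimated patient shift is
#' removed) with linear interpolation back onto the original position grid.
#' Samples falling outside the original support become `NA`.
#'
#' @param dpi A [transit_profile()].
#' @param shift_s Shift to remove \[cm\].
#' @return A [transit_profile()] on the same grid.
#' @export
resample_aligned <- function(dpi, shift_s) {
  if (shift_s == 0) return(dpi)
  s <- stats::approx(dpi$positions, dpi$signals,
                     xout = dpi$positions + shift_s, rule = 1)$y
  transit_profile(dpi$positions, s, meta = c(dpi$meta, list(aligned_shift = shift_s)))
}
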