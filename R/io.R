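#' Read and write density slices as plain-text grids
#'
#' The on-disk format is a whitespace-delimited numeric grid preceded by a
#' three-line header: `rows cols`, `spacing_cm`, `origin_x origin_y`. Rows of
#' the file correspond to rows of the grid (x along the beam).
#'
#' @param slice A [phantom_slice()].
#' @param path File path.
#' @param body_threshold Body threshold to attach on read.
#' @return `read_phantom_slice()` returns a [phantom_slice()];
#'   `write_phantom_slice()` returns `path` invisibly.
#' @export
write_phantom_slice <- function(slice, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste(nrow(slice$grid), ncol(slice$grid)),
               format(slice$spacing, digits = 12),
               paste(format(slice$origin, digits = 12), collapse = " ")), con)
  utils::write.table(slice$grid, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_phantom_slice
#' @export
read_phantom_slice <- function(path, body_threshold = 0.05) {
  hdr <- readLines(path, n = 3)
  dims <- as.integer(strsplit(trimws(hdr[1]), "\\s+")[[1]])
  spacing <- as.numeric(hdr[2])
  origin <- as.numeric(strsplit(trimws(hdr[3]), "\\s+")[[1]])
  vals <- utils::read.table(path, skip = 3)
  grid <- as.matrix(vals)
  dimnames(grid) <- NULL
  if (!all(dim(grid) == dims)) stop("grid dimensions do not match the header")
  phantom_slice(grid, spacing = spacing, origin = origin,
                body_threshold = body_threshold)
}

#' Read and write transit profiles as CSV
#'
#' CSV with columns `position_cm`, `signal_cu`, preceded by a block of
#' `# key: value` metadata lines.
#'
#' @param profile A [transit_profile()].
#' @param path File path.
#' @return `read_transit_profile()` returns a [transit_profile()];
#'   `write_transit_profile()` returns `path` invisibly.
#' @export
write_transit_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- profile$meta
  meta <- meta[vapply(meta, function(v) is.atomic(v) && length(v) == 1, logical(1))]
  for (k in names(meta)) writeLines(sprintf("# %s: %s", k, format(meta[[k]])), con)
  writeLines("position_cm,signal_cu", con)
  utils::write.table(
    data.frame(profile$positions, profile$signals), con,
    sep = ",", row.names = FALSE, col.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_transit_profile
#' @export
read_transit_profile <- function(path) {
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  meta <- list()
  for (l in lines[is_meta]) {
    kv <- sub("^#\\s*", "", l)
    k <- sub(":.*$", "", kv)
    v <- trimws(sub("^[^:]*:", "", kv))
    num <- suppressWarnings(as.numeric(v))
    meta[[trimws(k)]] <- if (is.na(num)) v else num
  }
  df <- utils::read.csv(text = paste(lines[!is_meta], collapse = "\n"))
  transit_profile(df$position_cm, df$signal_cu, meta = meta)
}

#' Read and write calibration sample tables as CSV
#'
#' Columns `w_cm`, `st_cu`, `dm_gy`, `wedge_deg`, `field_cm`, `r_cm`, `d_cm`
#' and optionally `kind`.
#'
#' @param samples Data frame of calibration samples.
#' @param path File path.
#' @return `read_calibration_samples()` returns the data frame;
#'   `write_calibration_samples()` returns `path` invisibly.
#' @export
write_calibration_samples <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calibration_samples
#' @export
read_calibration_samples <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Persist calibration models as YAML
#'
#' Writes/reads the bundled correlation and scatter models as a key-value
#' file with a `schema_version` field.
#'
#' @param calib An [epid_calibration()].
#' @param path File path.
#' @return `read_calibration()` returns an [epid_calibration()];
#'   `write_calibration()` returns `path` invisibly.
#' @export
write_calibration <- function(calib, path) {
  stopifnot(inherits(calib, "epid_calibration"))
  obj <- list(
    schema_version = 1L,
    correlation = list(
      a1 = calib$correlation$a1, a2 = calib$correlation$a2,
      a3 = calib$correlation$a3, valid_w = calib$correlation$valid_w,
      fit_residual_2sd = calib$correlation$fit_residual_2sd),
    scatter = list(
      radii = calib$scatter$radii, f0 = calib$scatter$f0,
      valid_d = calib$scatter$valid_d,
      fit_residual_2sd = calib$scatter$fit_residual_2sd))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  obj <- yaml::read_yaml(path)
  if (is.null(obj$schema_version) || obj$schema_version != 1L) {
    stop("unsupported calibration schema version")
  }
  nul2na <- function(x) if (is.null(x)) NA_real_ else x
  epid_calibration(
    correlation = correlation_model(
      a1 = obj$correlation$a1, a2 = obj$correlation$a2, a3 = obj$correlation$a3,
      valid_w = unlist(obj$correlation$valid_w),
      fit_residual_2sd = nul2na(obj$correlation$fit_residual_2sd)),
    scatter = scatter_model(
      radii = unlist(obj$scatter$radii), f0 = unlist(obj$scatter$f0),
      valid_d = unlist(obj$scatter$valid_d),
      fit_residual_2sd = nul2na(obj$scatter$fit_residual_2sd)))
}

#' Read a beam configuration file
#'
#' Key-value YAML with any of `sad`, `sed`, `field_length`, `field_width`,
#' `wedge_angle`, `gantry`; missing keys take the [beam_geometry()] defaults.
#'
#' @param path File path.
#' @return A [beam_geometry()].
#' @export
read_beam_config <- function(path) {
  obj <- yaml::read_yaml(path)
  args <- obj[names(obj) %in% names(formals(beam_geometry))]
  do.call(beam_geometry, args)
}

#' Write a dose profile as CSV
#'
#' Columns `position_cm`, `dose_gy`, `c_factor`, `excluded`, `reason`.
#'
#' @param dose A `dose_profile` from [profile_dose()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_dose_profile <- function(dose, path) {
  df <- data.frame(position_cm = dose$position, dose_gy = dose$dose,
                   c_factor = dose$c_factor, excluded = dose$excluded,
                   reason = dose$reason)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
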