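#' Measurement settings for lumen-visibility scoring
#'
#' @param roi_pixels Size of the homogeneity ROI in reconstructed pixels
#'   (default 120, >= 9).
#' @param vis_threshold_frac Fraction of the reference-lumen mean above which
#'   a pixel counts as visible lumen (default 0.5, the full-width-half-maximum
#'   convention for vessel delineation).
#' @param reference_margin Distance in mm between a stent end and the start
#'   of the unstented reference segment (default 5).
#' @return A `measurement_config` list.
#' @export
measurement_config <- function(roi_pixels = 120, vis_threshold_frac = 0.5,
                               reference_margin = 5) {
  if (roi_pixels < 9) abort("roi_pixels must be >= 9")
  if (vis_threshold_frac <= 0 || vis_threshold_frac >= 1) {
    abort("vis_threshold_frac must be in (0, 1)")
  }
  structure(list(roi_pixels = as.integer(roi_pixels),
                 vis_threshold_frac = vis_threshold_frac,
                 reference_margin = reference_margin),
            class = "measurement_config")
}

#' Extract the longitudinal mid-slice through the stent
#'
#' All three measurements are taken on the middle slice intersecting the
#' centre of the stent parallel to its long axis. The returned object
#' carries the 2D slice (tube cross-diameter x axial position), the pixel
#' rows lying on the lumen line, and the axial columns belonging to the
#' stented region and to the unstented reference segments (all lumen columns
#' at least `reference_margin` mm from either stent end, pooled from both
#' sides).
#'
#' @param image A `phantom_image`.
#' @param plane `"xz"` (default) or `"yz"`: which longitudinal plane through
#'   the tube axis to take. For a phantom the two are equivalent up to
#'   rasterization.
#' @param config A [measurement_config()].
#' @return A `mid_slice` object.
#' @export
extract_mid_slice <- function(image, plane = c("xz", "yz"),
                              config = measurement_config()) {
  plane <- match.arg(plane)
  vs <- attr(image, "voxel_size")
  geom <- attr(image, "geometry")
  d <- dim(image)
  if (plane == "xz") {
    yc <- (seq_len(d[2]) - 0.5) * vs[2]
    j <- which.min(abs(yc - geom$center_y))
    mat <- image[, j, ]
    off_mm <- (seq_len(d[1]) - 0.5) * vs[1] - geom$center_x
  } else {
    xc <- (seq_len(d[1]) - 0.5) * vs[1]
    i <- which.min(abs(xc - geom$center_x))
    mat <- image[i, , ]
    off_mm <- (seq_len(d[2]) - 0.5) * vs[2] - geom$center_y
  }
  z_mm <- (seq_len(d[3]) - 0.5) * vs[3]

  lumen_rows <- which(abs(off_mm) < geom$inner_radius)
  if (length(lumen_rows) < 3) abort("lumen narrower than 3 pixels on the reconstruction grid")

  z0 <- geom$stent_z[1]; z1 <- geom$stent_z[2]
  stent_cols <- which(z_mm >= z0 & z_mm < z1)
  if (length(stent_cols) < 3) abort("stented region shorter than 3 axial positions")
  m <- config$reference_margin
  ref_cols <- which(z_mm <= z0 - m | z_mm >= z1 + m)
  if (length(ref_cols) < ceiling(20 / length(lumen_rows))) {
    abort("stent touches the volume boundary: no unstented reference segment")
  }
  ref_mean <- mean(mat[lumen_rows, ref_cols])
  if (!is.finite(ref_mean) || ref_mean <= 0) abort("reference lumen signal is zero")

  structure(list(mat = mat, off_mm = off_mm, z_mm = z_mm,
                 lumen_rows = lumen_rows, stent_cols = stent_cols,
                 ref_cols = ref_cols, ref_mean = ref_mean,
                 pixel_mm = vs[1], geometry = geom,
                 provenance = attr(image, "provenance")),
            class = "mid_slice")
}

#' Relative in-stent signal intensity
#'
#' Mean lumen signal over the stented region as a percentage of the mean
#' lumen signal in the unstented reference segments, rounded to the nearest
#' integer percent. Values above 100 are possible (RF shielding moving the
#' effective flip angle towards the Ernst angle).
#'
#' @param slice A `mid_slice`.
#' @param config A [measurement_config()] (unused; kept for a uniform
#'   signature).
#' @return Integer-rounded percentage.
#' @export
relative_signal_intensity <- function(slice, config = measurement_config()) {
  stented <- mean(slice$mat[slice$lumen_rows, slice$stent_cols])
  round(100 * stented / slice$ref_mean)
}

#' Minimal and maximal visible lumen diameter
#'
#' At each axial position inside the stent the visible diameter is the
#' longest contiguous run of lumen-line pixels with signal at or above
#' `vis_threshold_frac` times the reference-lumen mean. The reference
#' diameter is the same quantity measured in the unstented segments (median
#' over reference positions), so an artifact-free stent scores exactly 100%.
#' A position with no pixel above threshold contributes 0 (signal
#' truncation).
#'
#' @inheritParams relative_signal_intensity
#' @return Named numeric vector `c(vis_min_percent, vis_max_percent)`,
#'   integer-rounded.
#' @export
visible_lumen_profile <- function(slice, config = measurement_config()) {
  thr <- config$vis_threshold_frac * slice$ref_mean
  runs <- function(cols) {
    vapply(cols, function(k) {
      longest_run(slice$mat[slice$lumen_rows, k] >= thr)
    }, numeric(1))
  }
  ref_d <- median(runs(slice$ref_cols))
  if (ref_d == 0) abort("no visible lumen in the reference segment")
  vis <- runs(slice$stent_cols)
  c(vis_min_percent = round(100 * min(vis) / ref_d),
    vis_max_percent = round(100 * max(vis) / ref_d))
}

longest_run <- function(b) {
  if (!any(b)) return(0)
  r <- rle(b)
  max(r$lengths[r$values])
}

#' Lumen signal homogeneity (SD/mean)
#'
#' Places a standardized rectangular ROI of `roi_pixels` reconstructed
#' pixels centred in the stented lumen (width limited to the lumen width
#' minus an edge pixel on each side, at most 8 pixels; length extended to
#' reach the pixel count) and returns the population standard deviation of
#' the ROI intensities divided by their mean, rounded to two decimals.
#'
#' @inheritParams relative_signal_intensity
#' @return SD/mean ratio, two decimals.
#' @export
lumen_homogeneity <- function(slice, config = measurement_config()) {
  w <- min(length(slice$lumen_rows) - 2, 8)
  if (w < 1) abort("lumen too narrow for a homogeneity ROI")
  rows <- centered_subset(slice$lumen_rows, w)
  len <- ceiling(config$roi_pixels / w)
  if (len > length(slice$stent_cols)) {
    len <- length(slice$stent_cols)
    if (w * len < config$roi_pixels) {
      warn(sprintf("stented lumen holds only %d pixels; ROI shrunk from %d",
                   w * len, config$roi_pixels))
    }
  }
  cols <- centered_subset(slice$stent_cols, len)
  px <- as.vector(slice$mat[rows, cols])
  px <- px[seq_len(min(length(px), config$roi_pixels))]
  if (length(px) < 9) abort("ROI smaller than 9 pixels")
  m <- mean(px)
  if (m == 0) abort("ROI mean is zero")
  round(sqrt(mean((px - m)^2)) / m, 2)
}

centered_subset <- function(idx, n) {
  start <- floor((length(idx) - n) / 2)
  idx[start + seq_len(n)]
}

#' Measure one simulated phantom
#'
#' Runs the full three-metric read-out on a phantom image and returns one
#' tidy row per the measurement-table schema.
#'
#' @param image A `phantom_image`.
#' @param config A [measurement_config()].
#' @param plane Longitudinal plane passed to [extract_mid_slice()].
#' @return A one-row tibble with columns `stent_id`, `name`, `si_percent`,
#'   `vis_min_percent`, `vis_max_percent`, `sd_over_mean`.
#' @export
measure_phantom <- function(image, config = measurement_config(),
                            plane = "xz") {
  sl <- extract_mid_slice(image, plane = plane, config = config)
  vis <- visible_lumen_profile(sl, config)
  p <- sl$provenance
  tibble(stent_id = p$stent_id %||% NA_integer_,
         name = p$stent_name %||% NA_character_,
         si_percent = relative_signal_intensity(sl, config),
         vis_min_percent = unname(vis[1]),
         vis_max_percent = unname(vis[2]),
         sd_over_mean = lumen_homogeneity(sl, config))
}
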