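#' Rasterize the phantom onto a fine voxel grid
#'
#' Builds the discrete 3D label map of one experiment: a gel block
#' (label 0) containing a plastic tube (wall, label 1) filled with Gd
#' solution (lumen, label 2) and carrying a stent (struts, label 3) centred
#' along the tube. The tube/stent axis is grid axis z, which by convention is
#' parallel to B0 (the phantom sits in the magnet centre aligned with the
#' scanner z-axis). Voxels are cubes of `grid_voxel` mm; physical coordinates
#' refer to voxel centres.
#'
#' Mesh and covered designs are rasterized as `n_helical_wires` helices with
#' alternating handedness and a pitch of one full turn per `length/6`;
#' slotted-tube designs as a perforated cylindrical shell (eight axial
#' slots); coil as a single helix. The shell thickness used for rasterization
#' is `max(strut_radius, 0.75 * grid_voxel)` so wires stay connected on
#' grids coarser than the physical strut.
#'
#' A stent wider than the tube is clamped to the tube's inner radius
#' (oversized deployment, as for a 6 mm stent in a 5 mm tube); more than
#' 2 mm of oversize is treated as a geometry error.
#'
#' @param tube A [tube_spec()].
#' @param stent A [stent_spec()].
#' @param grid_voxel Isotropic voxel edge in mm (default 0.25). Grids much
#'   coarser than the strut radius are allowed but logged.
#' @param pad Gel padding around the tube in x/y, mm (>= 5).
#' @return A `label_volume`: integer 3D array (x, y, z) with attributes
#'   `voxel_size` (mm), `stent_extent` (1-based index range along z),
#'   `geometry` (centre, radii, z extents in mm) and the two specs.
#' @examples
#' st <- stent_spec(4, "Absolute", "nitinol", 7, 60)
#' tb <- tube_for_stent(st)
#' vol <- rasterize_phantom(tb, st, grid_voxel = 0.5)
#' table(vol)
#' @export
rasterize_phantom <- function(tube, stent, grid_voxel = 0.25, pad = 5) {
  stopifnot(inherits(tube, "tube_spec"), inherits(stent, "stent_spec"))
  if (pad < 5) abort("pad must be >= 5 mm of gel on all sides")
  if (grid_voxel > 2 * stent$strut_radius) {
    inform(sprintf(
      "grid_voxel %.3g mm is coarser than twice the strut radius (%.3g mm); struts are rasterized as a %.3g mm shell",
      grid_voxel, stent$strut_radius, max(stent$strut_radius, 0.75 * grid_voxel)))
  }
  ri <- tube$inner_diameter / 2
  wt <- tube$wall_thickness
  if (stent$nominal_diameter / 2 > ri + 1) {
    abort(sprintf("stent diameter %g mm exceeds tube inner diameter %g mm by more than the 2 mm tolerance",
                  stent$nominal_diameter, tube$inner_diameter))
  }
  rs <- min(stent$nominal_diameter / 2, ri)  # clamp: oversized deployment
  if (tube$length < stent$length + 10) {
    abort("tube must be at least 10 mm longer than the stent to leave reference segments")
  }

  half_xy <- ri + wt + pad
  nx <- ceiling(2 * half_xy / grid_voxel)
  if (nx %% 2 == 1) nx <- nx + 1              # keep the axis mid-plane between voxels symmetric
  ny <- nx
  nz <- ceiling(tube$length / grid_voxel)
  cx <- nx * grid_voxel / 2
  cy <- ny * grid_voxel / 2
  x <- (seq_len(nx) - 0.5) * grid_voxel - cx
  y <- (seq_len(ny) - 0.5) * grid_voxel - cy
  z <- (seq_len(nz) - 0.5) * grid_voxel

  r2 <- outer(x^2, y^2, `+`)                  # nx x ny squared radius
  r <- sqrt(r2)
  wall_representable <- wt >= grid_voxel
  if (!wall_representable) {
    warn(sprintf("wall thickness %.3g mm is below one voxel (%.3g mm); wall omitted from the label map",
                 wt, grid_voxel))
  }
  xy_label <- matrix(0L, nx, ny)
  xy_label[r < ri] <- 2L
  if (wall_representable) xy_label[r >= ri & r < ri + wt] <- 1L
  labels <- array(xy_label, dim = c(nx, ny, nz))

  # stent extent along z, centred
  z0 <- (tube$length - stent$length) / 2
  z1 <- z0 + stent$length
  kz <- which(z >= z0 & z < z1)
  shell_t <- max(stent$strut_radius, 0.75 * grid_voxel)
  in_shell <- abs(r - rs) <= shell_t
  theta <- atan2(rep(y, each = nx), rep(x, times = ny))
  dim(theta) <- c(nx, ny)

  strut_xy_idx <- which(in_shell)
  if (length(strut_xy_idx) &&
      (stent$n_helical_wires > 0 || stent$design == "slotted_tube")) {
    th_shell <- theta[strut_xy_idx]
    for (k in kz) {
      zk <- z[k] - z0
      hit <- strut_mask_at(th_shell, zk, stent, rs, shell_t)
      if (any(hit)) {
        sl <- labels[, , k]
        sl[strut_xy_idx[hit]] <- 3L
        labels[, , k] <- sl
      }
    }
  }

  structure(labels,
            voxel_size = rep(grid_voxel, 3),
            stent_extent = range(kz),
            geometry = list(center_x = cx, center_y = cy,
                            inner_radius = ri, stent_radius = rs,
                            stent_z = c(z0, z1), tube_length = tube$length),
            tube = tube, stent = stent,
            class = c("label_volume", "array"))
}

# angular membership of struts at axial position zk (mm from stent start),
# given shell angles th (radians). Returns logical vector along th.
strut_mask_at <- function(th, zk, stent, rs, shell_t) {
  half_arc <- shell_t / rs                       # angular half-width of a wire
  if (stent$design == "slotted_tube") {
    # perforated shell: metal where cos(8*theta) > -0.2 (~63% metal),
    # mirror-symmetric in both x and y
    return(cos(8 * th) > -0.2)
  }
  n <- stent$n_helical_wires
  if (n == 0) return(rep(FALSE, length(th)))
  pitch <- stent$length / 6
  hit <- rep(FALSE, length(th))
  for (w in seq_len(n)) {
    handed <- if (stent$design == "coil") 1 else if (w %% 2 == 0) -1 else 1
    th_w <- handed * 2 * pi * zk / pitch + 2 * pi * (w - 1) / n
    d <- abs(((th - th_w + pi) %% (2 * pi)) - pi)
    hit <- hit | (d <= half_arc)
  }
  hit
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x)
  vs <- attr(x, "voxel_size")
  se <- attr(x, "stent_extent")
  cat(sprintf("<label_volume> %d x %d x %d voxels @ %g mm\n", d[1], d[2], d[3], vs[1]))
  cat(sprintf("  stent slices %d..%d; labels: %s\n", se[1], se[2],
              paste(names(table(x)), table(x), sep = "=", collapse = " ")))
  invisible(x)
}

#' Count voxels per tissue class
#'
#' @param labels A `label_volume`.
#' @return A tibble with columns `label`, `class`, `n_voxels`, `volume_mm3`.
#' @export
label_census <- function(labels) {
  vs <- prod(attr(labels, "voxel_size"))
  tab <- table(factor(as.integer(labels), levels = 0:3))
  tibble(label = 0:3,
         class = c("gel", "tube_wall", "lumen", "strut"),
         n_voxels = as.integer(tab),
         volume_mm3 = as.numeric(tab) * vs)
}
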