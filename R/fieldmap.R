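#' Susceptibility-induced B0 field map
#'
#' Forward dipole model of the static field perturbation caused by the stent
#' struts. The susceptibility map chi (strut voxels at the material's
#' `delta_chi`, zero elsewhere) is convolved with the z-oriented unit dipole
#' kernel
#' \deqn{K(\mathbf r) = \frac{V}{4\pi}\,\frac{3\cos^2\theta - 1}{|\mathbf r|^3},
#'   \qquad K(0) = 0,}
#' (V the voxel volume, theta the angle to B0 along grid axis z), sampled on
#' the periodic grid with minimal-image distances and applied by FFT. The
#' spatial mean of the result is removed (k = 0 convention), so the
#' perturbation averages to zero over the volume. Convolving in k-space with
#' the sampled kernel transform is exactly equivalent to a direct-space
#' dipole summation over all source voxels under periodic boundary
#' conditions, which is what the test oracle recomputes by brute force.
#'
#' @param labels A `label_volume` from [rasterize_phantom()].
#' @param material One-row tibble from [material_properties()], or a
#'   material key; only `delta_chi` is used.
#' @param B0 Field strength, tesla.
#' @return A `field_map`: 3D numeric array of off-resonance offsets in tesla
#'   on the same grid as `labels`, with `voxel_size` carried over.
#' @export
compute_field_map <- function(labels, material = attr(labels, "stent")$material,
                              B0 = 1.5) {
  if (is.character(material)) material <- material_properties(material)
  dchi <- material$delta_chi
  if (!is.finite(dchi)) abort("delta_chi must be finite")
  d <- dim(labels)
  if (any(d < 8)) abort("grid must be at least 8 voxels per axis for the dipole convolution")
  vs <- attr(labels, "voxel_size")
  if (dchi == 0 || !any(labels == 3L)) {
    db <- array(0, dim = d)
  } else {
    chi <- array(0, dim = d)
    chi[labels == 3L] <- dchi
    db <- B0 * dipole_convolve(chi, vs)
  }
  structure(db, voxel_size = vs, B0 = B0,
            class = c("field_map", "array"))
}

# periodic convolution of a susceptibility array with the discrete dipole
# kernel (B0 = 1); returns the zero-mean relative field offset
dipole_convolve <- function(chi, voxel_size) {
  d <- dim(chi)
  K <- dipole_kernel(d, voxel_size)
  out <- Re(fft(fft(chi) * fft(K), inverse = TRUE)) / prod(d)
  out - mean(out)
}

# z-oriented unit dipole kernel on the periodic grid, origin at [1,1,1]
dipole_kernel <- function(d, voxel_size) {
  dx <- min_image_offsets(d[1]) * voxel_size[1]
  dy <- min_image_offsets(d[2]) * voxel_size[2]
  dz <- min_image_offsets(d[3]) * voxel_size[3]
  r2 <- outer(outer(dx^2, dy^2, `+`), dz^2, `+`)
  z2 <- outer(array(0, dim = d[1:2]), dz^2, `+`)
  K <- prod(voxel_size) / (4 * pi) * (3 * z2 / r2 - 1) / r2^1.5
  K[1, 1, 1] <- 0                      # no self-field (Lorentz correction)
  K
}

# signed voxel offsets of a periodic axis, nearest-image convention
min_image_offsets <- function(n) {
  i <- seq(0, n - 1)
  ifelse(i > n / 2, i - n, i)
}
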