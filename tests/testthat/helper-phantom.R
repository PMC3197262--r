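# shared builders for simulated-phantom tests; coarse grids keep the suite fast

ghost_stent <- function(d = 7, len = 30) {
  stent_spec(99, "ghost", "none", d, len, n_helical_wires = 0)
}

# simulate a small phantom; material may be a key or a material_properties row
sim_phantom <- function(material = "none", d = 7, len = 30, grid = 0.5,
                        noise = 0, seed = 1, wires = 8, design = "mesh",
                        ref_len = 15, acq = NULL) {
  st <- if (identical(material, "none")) {
    ghost_stent(d, len)
  } else {
    stent_spec(1L, "test", material, d, len,
               n_helical_wires = wires, design = design)
  }
  tb <- tube_for_stent(st, reference_length = ref_len)
  vol <- suppressWarnings(suppressMessages(
    rasterize_phantom(tb, st, grid_voxel = grid)))
  acq <- acq %||% acquisition_params(noise_sigma = noise, seed = seed)
  simulate_image(vol, acq)
}

# multiply the signal of every pixel in the stented axial range by f; the
# lumen ratio then recovers f exactly (construct-and-recover oracle)
scale_in_stent <- function(img, f) {
  vs <- attr(img, "voxel_size")
  geom <- attr(img, "geometry")
  z <- (seq_len(dim(img)[3]) - 0.5) * vs[3]
  ks <- which(z >= geom$stent_z[1] & z < geom$stent_z[2])
  out <- img
  out[, , ks] <- out[, , ks] * f
  out
}

# hand-built longitudinal slice for metric oracles: lumen `lumen_px` pixels
# wide at `value`, gel at 0, stented columns in the middle
synthetic_slice <- function(n_off = 20, n_z = 60, lumen_px = 10, value = 1,
                            stent_cols = 21:40, pixel_mm = 0.55) {
  mat <- matrix(0, n_off, n_z)
  lumen_rows <- seq(floor((n_off - lumen_px) / 2) + 1, length.out = lumen_px)
  mat[lumen_rows, ] <- value
  structure(list(mat = mat,
                 off_mm = (seq_len(n_off) - 0.5) * pixel_mm,
                 z_mm = (seq_len(n_z) - 0.5) * pixel_mm,
                 lumen_rows = lumen_rows,
                 stent_cols = stent_cols,
                 ref_cols = setdiff(seq_len(n_z), (min(stent_cols) - 5):(max(stent_cols) + 5)),
                 ref_mean = mean(mat[lumen_rows,
                                     setdiff(seq_len(n_z),
                                             (min(stent_cols) - 5):(max(stent_cols) + 5))]),
                 pixel_mm = pixel_mm, geometry = NULL,
                 provenance = list(stent_id = 0L, stent_name = "synthetic")),
            class = "mid_slice")
}

# brute-force direct-space periodic dipole sum (independent of the FFT path):
# loops over source voxels and accumulates the z-dipole field at every voxel,
# nearest-image distances, demeaned
dipole_sum_direct <- function(chi, voxel = 1) {
  d <- dim(chi)
  mi <- function(v, n) (v + n %/% 2) %% n - n %/% 2
  out <- array(0, d)
  src <- which(chi != 0, arr.ind = TRUE)
  for (s in seq_len(nrow(src))) {
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      dx <- mi(i - src[s, 1], d[1]) * voxel
      dy <- mi(j - src[s, 2], d[2]) * voxel
      dz <- mi(k - src[s, 3], d[3]) * voxel
      r2 <- dx^2 + dy^2 + dz^2
      if (r2 == 0) next
      out[i, j, k] <- out[i, j, k] +
        chi[src[s, 1], src[s, 2], src[s, 3]] *
        voxel^3 / (4 * pi) * (3 * dz^2 / r2 - 1) / r2^1.5
    }
  }
  out - mean(out)
}

# wrap a bare susceptibility layout as a label_volume (strut label where
# chi_mask is TRUE) for compute_field_map
fake_label_volume <- function(chi_mask, voxel = 1) {
  labs <- array(0L, dim(chi_mask))
  labs[chi_mask] <- 3L
  structure(labs, voxel_size = rep(voxel, 3),
            stent_extent = c(1L, dim(chi_mask)[3]),
            class = c("label_volume", "array"))
}
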