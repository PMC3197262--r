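#' Simulate the contrast-enhanced MRA image of a stented phantom
#'
#' Synthesises the 3D spoiled gradient-echo image of a rasterized phantom.
#' Per fine voxel the steady-state SPGR amplitude is computed from the
#' label's T1/T2* (plastic wall and metal struts give no signal); inside the
#' stented lumen the nominal flip angle is multiplied by the material's
#' RF-shielding factor. Susceptibility effects enter through the dipole
#' field map: each fine voxel acquires a phase \eqn{2\pi\gamma\,\Delta B\,TE}
#' and, when `readout_bandwidth` is finite, is misregistered along the
#' readout (z) axis by \eqn{\gamma\,\Delta B / \mathrm{bw}} acquisition
#' voxels. Fine voxels are complex-summed into acquisition voxels (intravoxel
#' dephasing), complex Gaussian noise is added (Rician magnitude), and the
#' magnitude image is resampled to the reconstruction grid by trilinear
#' interpolation.
#'
#' @param labels A `label_volume` on the fine grid.
#' @param acq An [acquisition_params()].
#' @param stent,tube Override the specs carried by `labels` (rarely needed).
#' @return A `phantom_image`: 3D non-negative array on the reconstruction
#'   grid with attributes `voxel_size`, `geometry` (mm coordinates of the
#'   tube centre, inner radius, stent z-extent), `reference_level` (noise-free
#'   unstented-lumen signal) and `provenance`.
#' @examples
#' st <- stent_spec(99, "ghost", "none", 7, 30, n_helical_wires = 0)
#' tb <- tube_for_stent(st, reference_length = 15)
#' vol <- rasterize_phantom(tb, st, grid_voxel = 0.5)
#' img <- simulate_image(vol, acquisition_params(noise_sigma = 0, seed = 1))
#' @export
simulate_image <- function(labels, acq = acquisition_params(),
                           stent = attr(labels, "stent"),
                           tube = attr(labels, "tube")) {
  force(stent); force(tube)   # subsetting below drops the carrier attributes
  vs <- attr(labels, "voxel_size")
  geom <- attr(labels, "geometry")
  d <- dim(labels)

  fac <- acq$acq_voxel / vs
  if (any(abs(fac - round(fac)) > 1e-8)) {
    warn(sprintf("fine grid (%g mm) is not an integer subdivision of the acquisition voxel (%g mm); regridding factor rounded",
                 vs[1], acq$acq_voxel))
  }
  fac <- pmax(1L, as.integer(round(fac)))
  keep <- (d %/% fac) * fac
  if (any(keep < d)) {
    # centre-crop to a multiple of the downsampling factor
    off <- (d - keep) %/% 2
    labels <- labels[off[1] + seq_len(keep[1]),
                     off[2] + seq_len(keep[2]),
                     off[3] + seq_len(keep[3]), drop = FALSE]
    geom$center_x <- geom$center_x - off[1] * vs[1]
    geom$center_y <- geom$center_y - off[2] * vs[2]
    geom$stent_z <- geom$stent_z - off[3] * vs[3]
    geom$tube_length <- keep[3] * vs[3]
    d <- keep
    attr(labels, "voxel_size") <- vs
  }

  # per-voxel relaxation and effective flip
  T1 <- array(tube$background_T1, dim = d)
  T2 <- array(tube$background_T2star, dim = d)
  lum <- labels == 2L
  T1[lum] <- tube$lumen_T1
  T2[lum] <- tube$lumen_T2star

  flip <- array(acq$flip_deg, dim = d)
  sf <- stent$material$shielding_factor
  if (sf != 1) {
    x <- (seq_len(d[1]) - 0.5) * vs[1] - geom$center_x
    y <- (seq_len(d[2]) - 0.5) * vs[2] - geom$center_y
    z <- (seq_len(d[3]) - 0.5) * vs[3]
    inside_r <- outer(x^2, y^2, `+`) < geom$stent_radius^2
    in_z <- z >= geom$stent_z[1] & z < geom$stent_z[2]
    shield <- outer(inside_r, in_z, `&`) & lum
    flip[shield] <- acq$flip_deg * sf
  }

  amp <- spgr_signal(T1, T2, acq, flip)
  amp[labels == 1L | labels == 3L] <- 0      # plastic and metal: no signal

  # susceptibility: phase and readout misregistration
  dchi <- stent$material$delta_chi
  if (dchi > 0 && any(labels == 3L)) {
    fm <- compute_field_map(labels, stent$material, acq$B0)
    phase <- 2 * pi * GAMMA_HZ_PER_T * as.numeric(fm) * (acq$TE / 1000)
    sig <- amp * complex(real = cos(phase), imaginary = sin(phase))
    if (is.finite(acq$readout_bandwidth)) {
      shift_mm <- GAMMA_HZ_PER_T * as.numeric(fm) / acq$readout_bandwidth * acq$acq_voxel
      sig <- shift_along_z(sig, round(shift_mm / vs[3]))
    }
  } else {
    sig <- amp * (1 + 0i)
  }

  # intravoxel dephasing: complex block mean onto the acquisition grid
  acq_img <- block_mean_3d(sig, fac)

  # reference signal level: noise-free unstented lumen amplitude
  ref_level <- spgr_signal(tube$lumen_T1, tube$lumen_T2star, acq, acq$flip_deg)

  if (acq$noise_sigma > 0) {
    s <- acq$noise_sigma * ref_level
    noise <- with_seed_if(acq$seed, {
      n <- length(acq_img)
      complex(real = rnorm(n, 0, s), imaginary = rnorm(n, 0, s))
    })
    acq_img <- acq_img + noise
  }
  mag <- Mod(acq_img)

  out_vox <- rep(acq$recon_voxel, 3)
  recon <- resample_trilinear(mag, voxel_in = rep(acq$acq_voxel, 3),
                              voxel_out = out_vox)

  structure(recon,
            voxel_size = out_vox,
            geometry = geom,
            reference_level = ref_level,
            provenance = list(stent_id = stent$id, stent_name = stent$name,
                              material = stent$material$name, acq = acq,
                              seed = acq$seed,
                              package = as.character(packageVersion("stentmra"))),
            class = c("phantom_image", "array"))
}

#' @export
print.phantom_image <- function(x, ...) {
  d <- dim(x)
  p <- attr(x, "provenance")
  cat(sprintf("<phantom_image> %d x %d x %d @ %g mm  (stent #%s %s)\n",
              d[1], d[2], d[3], attr(x, "voxel_size")[1],
              p$stent_id, p$stent_name))
  invisible(x)
}

# displace complex voxel contributions along z by an integer number of fine
# voxels (readout misregistration); contributions falling on the same target
# voxel add coherently
shift_along_z <- function(sig, shift_vox) {
  moving <- which(shift_vox != 0)
  if (!length(moving)) return(sig)
  d <- dim(sig)
  nz <- d[3]
  per_slice <- d[1] * d[2]
  idx0 <- moving - 1L
  zi <- idx0 %/% per_slice
  zt <- pmin(pmax(zi + shift_vox[moving], 0L), nz - 1L)
  tgt <- (idx0 %% per_slice) + zt * per_slice + 1L
  out <- sig
  out[moving] <- 0
  add <- rowsum(cbind(Re(sig[moving]), Im(sig[moving])), group = tgt)
  at <- as.integer(rownames(add))
  out[at] <- out[at] + complex(real = add[, 1], imaginary = add[, 2])
  out
}

# block average a 3D array by integer factors (complex-safe)
block_mean_3d <- function(a, fac) {
  d <- dim(a)
  d2 <- d %/% fac
  dim(a) <- c(fac[1], d2[1], fac[2], d2[2], fac[3], d2[3])
  a <- aperm(a, c(1, 3, 5, 2, 4, 6))
  dim(a) <- c(prod(fac), prod(d2))
  out <- colMeans(a)
  dim(out) <- d2
  out
}

# separable trilinear resampling between isotropic-ish grids (mm-aligned,
# voxel centres at (i - 0.5) * voxel); constant extrapolation at the edges
resample_trilinear <- function(a, voxel_in, voxel_out) {
  for (ax in 1:3) {
    d <- dim(a)
    n_in <- d[ax]
    extent <- n_in * voxel_in[ax]
    n_out <- max(2L, floor(extent / voxel_out[ax]))
    xi <- (seq_len(n_in) - 0.5) * voxel_in[ax]
    xo <- (seq_len(n_out) - 0.5) * voxel_out[ax]
    a <- interp_along(a, ax, xi, xo)
  }
  a
}

interp_along <- function(a, ax, xi, xo) {
  d <- dim(a)
  perm <- c(ax, setdiff(1:3, ax))
  m <- aperm(a, perm)
  dim(m) <- c(d[ax], prod(d[-ax]))
  out <- apply(m, 2, function(col) {
    approx(xi, col, xout = xo, rule = 2)$y
  })
  dim(out) <- c(length(xo), d[setdiff(1:3, ax)])
  aperm(out, order(perm))
}

# evaluate expr under a fixed RNG seed without disturbing the caller's stream
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
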