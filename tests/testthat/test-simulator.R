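test_that("an artifact-free phantom reproduces the unstented signal identically", {
  img <- sim_phantom(noise = 0)
  m <- measure_phantom(img)
  expect_equal(m$si_percent, 100)
  expect_equal(m$vis_min_percent, 100)
  expect_equal(m$vis_max_percent, 100)
  expect_equal(m$sd_over_mean, 0)
  # arterial contrast: lumen brighter than gel
  sl <- extract_mid_slice(img)
  gel_rows <- setdiff(seq_len(nrow(sl$mat)), sl$lumen_rows)
  expect_gt(mean(sl$mat[sl$lumen_rows, ]), mean(sl$mat[gel_rows, ]))
  expect_true(all(img >= 0))
})

test_that("noisy simulations are bit-identical under the same seed", {
  a <- sim_phantom("nitinol", noise = 0.02, seed = 11)
  b <- sim_phantom("nitinol", noise = 0.02, seed = 11)
  expect_identical(as.numeric(a), as.numeric(b))
  c <- sim_phantom("nitinol", noise = 0.02, seed = 12)
  expect_false(identical(as.numeric(a), as.numeric(c)))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(42); before <- rnorm(1)
  set.seed(42); invisible(sim_phantom("nitinol", noise = 0.02, seed = 5))
  expect_identical(rnorm(1), before)
})

test_that("RF shielding towards the Ernst angle lifts in-stent signal above 100%", {
  mat <- material_properties("cobalt_superalloy", delta_chi = 0)  # pure B1 effect
  img <- sim_phantom(mat, len = 40, noise = 0)
  m <- measure_phantom(img)
  expect_gt(m$si_percent, 100)
})

test_that("artifact severity is monotone in the susceptibility difference", {
  chis <- c(190e-6, 255e-6, 290e-6, 3e-3)   # Ta, nitinol, Pt, 316L
  res <- lapply(chis, function(dc) {
    mat <- material_properties("nitinol", delta_chi = dc, shielding_factor = 1)
    measure_phantom(sim_phantom(mat, len = 40, noise = 0.02, seed = 5))
  })
  res <- do.call(rbind, res)
  expect_true(all(diff(res$vis_min_percent) <= 0))
  expect_true(all(diff(res$sd_over_mean) >= 0))
  # fraction of in-stent lumen pixels below half the reference also grows
  frac_low <- vapply(chis, function(dc) {
    mat <- material_properties("nitinol", delta_chi = dc, shielding_factor = 1)
    img <- sim_phantom(mat, len = 40, noise = 0)
    sl <- extract_mid_slice(img)
    mean(sl$mat[sl$lumen_rows, sl$stent_cols] < 0.5 * sl$ref_mean)
  }, numeric(1))
  expect_true(all(diff(frac_low) >= 0))
})

test_that("a fine grid that does not subdivide the acquisition voxel warns and regrids", {
  st <- ghost_stent(7, 30)
  tb <- tube_for_stent(st, reference_length = 15)
  vol <- suppressWarnings(suppressMessages(
    rasterize_phantom(tb, st, grid_voxel = 0.4)))
  expect_warning(simulate_image(vol, acquisition_params(noise_sigma = 0)),
                 "integer subdivision")
})
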