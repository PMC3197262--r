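test_that("known in-stent attenuation factors are recovered exactly", {
  img <- sim_phantom(noise = 0)
  for (f in c(0.06, 0.45, 0.80)) {
    m <- measure_phantom(scale_in_stent(img, f))
    expect_equal(m$si_percent, round(100 * f))
  }
  # a uniform 1.17 in-stent factor reads as 117%
  expect_equal(measure_phantom(scale_in_stent(img, 1.17))$si_percent, 117)
})

test_that("measurements are invariant to the longitudinal plane chosen", {
  img <- sim_phantom("nitinol", len = 40, noise = 0.02, seed = 3)
  m1 <- measure_phantom(img, plane = "xz")
  m2 <- measure_phantom(img, plane = "yz")
  expect_lt(abs(m1$si_percent - m2$si_percent), 3)
})

test_that("ratio metrics are invariant to global intensity rescaling", {
  img <- sim_phantom("nitinol", len = 40, noise = 0.02, seed = 9)
  scaled <- img
  scaled[] <- scaled[] * 37.5
  expect_equal(measure_phantom(img)$si_percent,
               measure_phantom(scaled)$si_percent)
  expect_equal(measure_phantom(img)$sd_over_mean,
               measure_phantom(scaled)$sd_over_mean)
})

test_that("rectangular voids shrink the visible lumen by their width", {
  sl <- synthetic_slice(lumen_px = 10)
  expect_equal(unname(visible_lumen_profile(sl)), c(100, 100))

  # a void occluding 40% of the lumen width at one position -> vis_min 60
  sl$mat[sl$lumen_rows[1:4], 30] <- 0
  v <- visible_lumen_profile(sl)
  expect_equal(unname(v), c(60, 100))

  # full-width signal void -> truncation, vis_min 0
  sl$mat[sl$lumen_rows, 25] <- 0
  expect_equal(unname(visible_lumen_profile(sl))[1], 0)
})

test_that("interior voids count only their longest contiguous visible run", {
  sl <- synthetic_slice(lumen_px = 10)
  sl$mat[sl$lumen_rows[5:6], 30] <- 0     # central void splits the lumen line
  expect_equal(unname(visible_lumen_profile(sl))[1], 40)  # runs of 4 and 4
})

test_that("homogeneity matches hand-computed distributions", {
  sl <- synthetic_slice(lumen_px = 10, stent_cols = 21:35)  # 8 x 15 ROI = 120
  expect_equal(lumen_homogeneity(sl), 0)

  # two-point distribution: 60 pixels at a, 60 at 3a -> population SD/mean 0.5
  rows <- centered <- sl$lumen_rows[2:9]
  sl2 <- sl
  sl2$mat[rows[1:4], sl2$stent_cols] <- 1
  sl2$mat[rows[5:8], sl2$stent_cols] <- 3
  expect_equal(lumen_homogeneity(sl2), 0.5)
})

test_that("homogeneity ROI recovers the simulated noise level", {
  img <- sim_phantom(noise = 0.02, seed = 21, len = 40)
  m <- measure_phantom(img)
  expect_lt(abs(m$sd_over_mean - 0.02), 0.011)
})

test_that("degenerate geometries are rejected", {
  img <- sim_phantom(noise = 0)
  # pretend the stent spans the whole tube: no reference segment left
  attr(img, "geometry")$stent_z <- c(0, attr(img, "geometry")$tube_length)
  expect_error(extract_mid_slice(img), "reference")

  sl <- synthetic_slice()
  sl$stent_cols <- 21:22
  expect_error(
    measure_phantom(sim_phantom(noise = 0, len = 1.2)), "3 axial")
})
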