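test_that("label classes partition the grid and the stent spans its nominal length", {
  st <- stent_spec(4, "Absolute-like", "nitinol", 7, 60)
  tb <- tube_for_stent(st)
  vol <- suppressMessages(rasterize_phantom(tb, st, grid_voxel = 0.25))

  expect_true(all(as.integer(vol) %in% 0:3))
  se <- attr(vol, "stent_extent")
  expect_equal(diff(se) + 1L, 240L)  # 60 mm / 0.25 mm

  # every strut voxel sits within one voxel of the inner-wall radius
  geom <- attr(vol, "geometry")
  idx <- which(vol == 3L, arr.ind = TRUE)
  expect_gt(nrow(idx), 0)
  x <- (idx[, 1] - 0.5) * 0.25 - geom$center_x
  y <- (idx[, 2] - 0.5) * 0.25 - geom$center_y
  r <- sqrt(x^2 + y^2)
  expect_true(all(abs(r - geom$stent_radius) <= 0.25 + 1e-9))
  # and within the stent extent along z
  expect_true(all(idx[, 3] >= se[1] & idx[, 3] <= se[2]))
})

test_that("a stent with no wires leaves the tube label map unstented", {
  st <- ghost_stent(7, 30)
  tb <- tube_for_stent(st, reference_length = 15)
  vol <- suppressWarnings(suppressMessages(
    rasterize_phantom(tb, st, grid_voxel = 0.5)))
  expect_false(any(vol == 3L))

  meshed <- stent_spec(1, "meshed", "nitinol", 7, 30)
  vol2 <- suppressMessages(suppressWarnings(
    rasterize_phantom(tb, meshed, grid_voxel = 0.5)))
  # removing the struts recovers the unstented map
  vol2_nostrut <- vol2
  vol2_nostrut[vol2 == 3L] <- vol[vol2 == 3L]
  expect_equal(as.integer(vol2_nostrut), as.integer(vol))
})

test_that("rasterized lumen volume converges to the analytic cylinder volume", {
  st <- ghost_stent(5, 50)
  tb <- tube_spec(5, 100)
  analytic <- pi * 2.5^2 * 100
  err <- vapply(c(0.5, 0.25), function(g) {
    vol <- suppressMessages(suppressWarnings(
      rasterize_phantom(tb, st, grid_voxel = g)))
    abs(sum(vol == 2L) * g^3 - analytic) / analytic
  }, numeric(1))
  expect_lt(err[2], 0.02)            # 0.25 mm grid within 2%
  expect_lt(err[2], err[1] / 2)      # error at least halves with resolution
})

test_that("slotted-tube designs rasterize mirror-symmetrically about the axis", {
  st <- stent_spec(1, "slotted", "316L", 7, 20, design = "slotted_tube")
  tb <- tube_for_stent(st, reference_length = 10)
  vol <- suppressMessages(rasterize_phantom(tb, st, grid_voxel = 0.25))
  a <- unclass(vol); attributes(a) <- list(dim = dim(vol))
  flipped_x <- a[rev(seq_len(dim(a)[1])), , ]
  flipped_y <- a[, rev(seq_len(dim(a)[2])), ]
  expect_identical(a, flipped_x)
  expect_identical(a, flipped_y)
})

test_that("oversized stents are clamped to the tube and gross mismatch errors", {
  # 6 mm stent deployed in a 5 mm tube (oversized deployment)
  st <- stent_spec(3, "Genesis-like", "316L", 6, 39, design = "slotted_tube")
  tb <- tube_spec(5, 80)
  vol <- suppressMessages(rasterize_phantom(tb, st, grid_voxel = 0.25))
  expect_equal(attr(vol, "geometry")$stent_radius, 2.5)

  st_big <- stent_spec(22, "too-big", "platinum_alloy", 13, 28)
  expect_error(rasterize_phantom(tube_spec(8, 60), st_big, grid_voxel = 0.5),
               "tolerance")
})

test_that("a wall thinner than one voxel is omitted with a warning", {
  st <- ghost_stent(7, 30)
  tb <- tube_for_stent(st, reference_length = 15)   # wall 0.25 mm
  expect_warning(rasterize_phantom(tb, st, grid_voxel = 0.5), "wall omitted")
  vol <- suppressWarnings(rasterize_phantom(tb, st, grid_voxel = 0.5))
  expect_false(any(vol == 1L))
})

test_that("padding below 5 mm of gel is rejected", {
  st <- ghost_stent()
  expect_error(rasterize_phantom(tube_for_stent(st), st, grid_voxel = 0.5,
                                 pad = 2), "pad")
})
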