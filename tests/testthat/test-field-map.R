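test_that("zero susceptibility gives an identically zero field", {
  mask <- array(FALSE, c(8, 8, 8)); mask[4, 4, 4] <- TRUE
  vol <- fake_label_volume(mask)
  fm <- compute_field_map(vol, material_properties("nitinol", delta_chi = 0))
  expect_true(all(fm == 0))
  # and a volume with no strut voxels
  vol0 <- fake_label_volume(array(FALSE, c(8, 8, 8)))
  expect_true(all(compute_field_map(vol0, "316L") == 0))
})

test_that("single-source FFT field matches a brute-force dipole sum within 5%", {
  mask <- array(FALSE, c(8, 8, 8)); mask[4, 4, 4] <- TRUE
  vol <- fake_label_volume(mask)
  mat <- material_properties("nitinol")      # delta_chi 255e-6
  fm <- compute_field_map(vol, mat, B0 = 1.5)

  chi <- array(0, c(8, 8, 8)); chi[4, 4, 4] <- mat$delta_chi
  oracle <- 1.5 * dipole_sum_direct(chi, voxel = 1)

  away <- array(TRUE, c(8, 8, 8)); away[4, 4, 4] <- FALSE
  meaningful <- away & abs(oracle) > 1e-12
  rel <- abs(fm[meaningful] - oracle[meaningful]) / abs(oracle[meaningful])
  expect_lt(max(rel), 0.05)

  # dipole sign structure: positive along B0 above the source, negative beside
  expect_gt(fm[4, 4, 5], 0)
  expect_lt(fm[5, 4, 4], 0)
  expect_true(sign(fm[4, 4, 5]) != sign(fm[5, 4, 4]))
})

test_that("the field is linear in delta_chi and has zero spatial mean", {
  mask <- array(FALSE, c(8, 8, 8))
  mask[c(200, 231, 310)] <- TRUE            # a few scattered sources
  vol <- fake_label_volume(mask)
  f1 <- compute_field_map(vol, material_properties("none", delta_chi = 1e-4))
  f2 <- compute_field_map(vol, material_properties("none", delta_chi = 2e-4))
  expect_equal(as.numeric(f2), 2 * as.numeric(f1), tolerance = 1e-12)
  expect_lt(abs(mean(f1)), 1e-18)
})

test_that("non-finite susceptibility is rejected", {
  mask <- array(FALSE, c(8, 8, 8)); mask[4, 4, 4] <- TRUE
  vol <- fake_label_volume(mask)
  bad <- material_properties("nitinol")
  bad$delta_chi <- NaN
  expect_error(compute_field_map(vol, bad), "finite")
})
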