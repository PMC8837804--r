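# small shared reconstruction setup: water cylinder, full orbit
.recon_fix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      geom <- desk_geometry(angles = seq(0, 357, by = 3), n = 48,
                            pitch_mm = 2.5)
      cyl <- make_cylinder_phantom(16, 36, fix_water(),
                                   dim = c(168, 108, 108))
      grid <- desk_grid(48, 0.5)
      mono <- project_mono(cyl, geom, 35)
      cache <<- list(geom = geom, cyl = cyl, grid = grid, mono = mono,
                     vol = fdk_reconstruct(mono, grid))
    }
    cache
  }
})

test_that("FDK of zero projections is zero and FDK is linear", {
  fx <- .recon_fix()
  zero <- fx$mono
  zero$images[] <- 0
  expect_equal(max(abs(fdk_reconstruct(zero, fx$grid)$values)), 0)

  doubled <- fx$mono
  doubled$images <- 2 * doubled$images
  v2 <- fdk_reconstruct(doubled, fx$grid)
  expect_equal(v2$values, 2 * fx$vol$values, tolerance = 1e-10)
})

test_that("FDK of noise-free mono projections recovers mu_water(35 keV)", {
  fx <- .recon_fix()
  roi <- cylinder_roi(fx$grid, radius_mm = 5, half_length_mm = 10)
  mu_ref <- material_mu(fix_water(), 35)
  expect_rel_equal(mean(fx$vol$values[roi]), mu_ref, 0.03)

  # central in-plane profile across the cylinder: flat within 2%
  prof <- central_slice_profile(fx$vol, c(0, -6, 0), c(0, 6, 0), n = 49)
  expect_lt(diff(range(prof$value)) / mean(prof$value), 0.02)
})

test_that("reconstruction of a symmetric phantom is rotationally symmetric", {
  fx <- .recon_fix()
  py <- central_slice_profile(fx$vol, c(0, -6, 0), c(0, 6, 0), n = 25)
  pz <- central_slice_profile(fx$vol, c(0, 0, -6), c(0, 0, 6), n = 25)
  expect_equal(py$value, pz$value, tolerance = 0.02)
})

test_that("polyenergetic reconstruction cups and is less uniform", {
  fx <- .recon_fix()
  poly <- project_poly(fx$cyl, fx$geom)
  vraw <- fdk_reconstruct(poly, fx$grid)

  # cupping: center mean below peripheral-interior mean
  ctr <- cylinder_roi(fx$grid, radius_mm = 2, half_length_mm = 8)
  ring <- cylinder_roi(fx$grid, radius_mm = 6.5, half_length_mm = 8) &
    !cylinder_roi(fx$grid, radius_mm = 4.5, half_length_mm = 8)
  ratio_poly <- mean(vraw$values[ctr]) / mean(vraw$values[ring])
  expect_lt(ratio_poly, 1)
  ratio_mono <- mean(fx$vol$values[ctr]) / mean(fx$vol$values[ring])
  expect_gt(ratio_mono, ratio_poly)
  expect_lt(abs(ratio_mono - 1), abs(ratio_poly - 1))

  # profile signature: center below the edge-adjacent interior
  prof <- central_slice_profile(vraw, c(0, -7, 0), c(0, 7, 0), n = 49)
  inner <- prof$value[23:27]
  near_edge <- prof$value[c(4:6, 44:46)]
  expect_lt(mean(inner), mean(near_edge))

  # uniformity ordering on the same ROI
  roi <- cylinder_roi(fx$grid, radius_mm = 5, half_length_mm = 10)
  expect_lt(unaad(vraw, roi), unaad(fx$vol, roi))
})

test_that("reconstruction rejects inconsistent inputs", {
  fx <- .recon_fix()
  few <- fx$mono
  few$images <- few$images[, , 1:2]
  few$angles <- few$angles[1:2]
  expect_error(fdk_reconstruct(few, fx$grid), "angular coverage")

  one <- fx$mono
  one$images <- one$images[, , 1, drop = FALSE]
  one$angles <- one$angles[1]
  expect_error(fdk_reconstruct(one, fx$grid), "at least 2")

  bad <- fx$mono
  bad$geometry <- desk_geometry(angles = bad$angles, n = 64)
  expect_error(fdk_reconstruct(bad, fx$grid), "mismatch")
})

test_that("profiles interpolate volumes and respect bounds", {
  vol <- new_volume(array(2.5, c(10, 10, 10)), rep(1, 3), rep(-5, 3))
  prof <- central_slice_profile(vol, c(-3, 0, 0), c(3, 0, 0), n = 13)
  expect_equal(prof$value, rep(2.5, 13))
  expect_equal(max(prof$s_mm), 6)
  expect_error(central_slice_profile(vol, c(0, 0, 0), c(20, 0, 0)),
               "leaves the volume")
})

test_that("volume NIfTI round trip keeps values and spacing", {
  fx <- .recon_fix()
  f <- file.path(withr::local_tempdir(), "vol.nii.gz")
  write_volume(fx$vol, f)
  v2 <- read_volume(f)
  expect_equal(v2$values, fx$vol$values, tolerance = 1e-6)
  expect_equal(v2$voxel_size, fx$vol$voxel_size, tolerance = 1e-6)
})
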