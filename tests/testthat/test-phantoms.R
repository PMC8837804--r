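test_that("cylinder phantom volume matches the analytic cylinder", {
  d <- 10; len <- 20
  ph <- make_cylinder_phantom(d, len, fix_water(), dim = c(128, 96, 96))
  vol_vox <- sum(ph$labels == 1L) * prod(ph$voxel_size)
  expect_rel_equal(vol_vox, pi * (d / 2)^2 * len, 0.03)

  # rotating 90 degrees about z on a symmetric grid preserves the volume
  ph90 <- make_cylinder_phantom(d, len, fix_water(), orientation = c(0, 1, 0),
                                dim = c(96, 128, 96))
  expect_rel_equal(sum(ph90$labels == 1L), sum(ph$labels == 1L), 0.01)

  expect_error(make_cylinder_phantom(0.1, 0.1, fix_water(),
                                     voxel_size = rep(0.5, 3)),
               "degenerate")
  expect_error(make_cylinder_phantom(10, 500, fix_water()),
               "exceeds the voxel grid")
})

test_that("every grid label has a material and label 0 is air", {
  ph <- fix_cylinder()
  expect_true(all(as.character(sort(unique(as.vector(ph$labels))))
                  %in% names(ph$materials)))
  expect_equal(ph$materials[["0"]]$name, "air")
  expect_error(voxel_phantom(array(5L, c(2, 2, 2)), rep(1, 3),
                             list("1" = fix_water())),
               "labels without material")
})

test_that("mouse phantom is deterministic, diverse and anatomically connected", {
  m1 <- make_mouse_phantom(7, water_tube = TRUE)
  m2 <- make_mouse_phantom(7, water_tube = TRUE)
  expect_identical(m1$labels, m2$labels)

  # at least 8 distinct tissue labels beyond air
  expect_gte(length(setdiff(unique(as.vector(m1$labels)), 0L)), 8)

  # the skeleton (trabecular spine + cortical skull) forms one
  # connected component
  bone <- m1$labels == 3L | m1$labels == 12L
  comp <- label_components(bone)
  expect_equal(max(comp), 1)

  # skeleton spans most of the body axis
  xs <- which(apply(bone, 1, any))
  expect_gt(diff(range(xs)) * m1$voxel_size[1], 40)
})

test_that("head lift displaces the head centroid along z", {
  m0 <- make_mouse_phantom(3, head_lift_mm = 0)
  m5 <- make_mouse_phantom(3, head_lift_mm = 5)
  zc <- function(m) {
    idx <- which(m$labels == 4L, arr.ind = TRUE)  # brain
    mean(m$origin[3] + (idx[, 3] - 0.5) * m$voxel_size[3])
  }
  expect_equal(zc(m5) - zc(m0), 5, tolerance = 0.15)
})

test_that("augmentation is identity for zero ranges and respects invariants", {
  ph <- fix_cylinder()
  id_spec <- augmentation_spec(voxel_range = rep(ph$voxel_size[1], 2),
                               translation_mm = 0, angle_range = c(0, 0),
                               rel_comp = 0, rel_density = 0, seed = 9)
  out <- augment(ph, id_spec)
  expect_equal(out$angle, 0)
  expect_equal(out$phantom$voxel_size, ph$voxel_size)
  expect_equal(out$phantom$origin, ph$origin)
  expect_identical(out$phantom$labels, ph$labels)
  expect_equal(out$phantom$materials[["1"]]$composition,
               ph$materials[["1"]]$composition)

  spec <- augmentation_spec(seed = 4)
  out <- augment(ph, spec)
  for (m in out$phantom$materials) {
    expect_equal(sum(m$composition), 1, tolerance = 1e-9)
    expect_true(all(m$composition >= 0))
    expect_gt(m$density, 0)
  }
  # determinism
  out2 <- augment(ph, spec)
  expect_identical(out$phantom$voxel_size, out2$phantom$voxel_size)
  expect_identical(out$angle, out2$angle)
})

test_that("sampled voxel sizes fill the configured range uniformly", {
  ph <- make_cylinder_phantom(6, 6, fix_water(), dim = c(48, 48, 48))
  vox <- t(vapply(1:1000, function(i) {
    augment(ph, augmentation_spec(seed = i))$phantom$voxel_size
  }, numeric(3)))
  expect_gte(min(vox), 0.17)
  expect_lte(max(vox), 0.29)
  # mean of 3000 uniform draws: within 3 sigma of the midpoint
  se <- (0.29 - 0.17) / sqrt(12) / sqrt(length(vox))
  expect_lt(abs(mean(vox) - 0.23), 3 * se)
})

test_that("dataset enumeration produces the requested corpus", {
  expect_length(make_dataset(1, 1, 0, seed = 1), 1)
  specs <- make_dataset(2, 3, 4, seed = 1)
  expect_length(specs, 10)
  expect_length(unique(vapply(specs, `[[`, 0, "aug_seed")), 10)
  # reproducible from the master seed alone
  specs2 <- make_dataset(2, 3, 4, seed = 1)
  expect_identical(specs, specs2)
  expect_false(identical(specs, make_dataset(2, 3, 4, seed = 2)))
})

test_that("phantom NIfTI + sidecar round trip preserves everything", {
  ph <- make_cylinder_phantom(8, 10, fix_water(), dim = c(64, 48, 48))
  f <- file.path(withr::local_tempdir(), "ph.nii.gz")
  write_phantom(ph, f)
  ph2 <- read_phantom(f)
  expect_identical(ph2$labels, ph$labels)
  expect_equal(ph2$voxel_size, ph$voxel_size, tolerance = 1e-6)
  expect_equal(ph2$origin, ph$origin, tolerance = 1e-6)
  expect_equal(ph2$materials[["1"]]$composition,
               ph$materials[["1"]]$composition, tolerance = 1e-6)
})
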