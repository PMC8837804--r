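# Shared fixtures, built lazily and cached per test file.

.fix <- new.env()

fix_water <- function() material_library()$water

# small water cylinder along x, fits the desk detector FOV
fix_cylinder <- function() {
  if (is.null(.fix$cyl)) {
    .fix$cyl <- make_cylinder_phantom(16, 40, fix_water(),
                                      dim = c(192, 120, 120))
  }
  .fix$cyl
}

# centered water sphere, radius mm, built directly on a voxel grid
make_sphere_phantom <- function(radius_mm = 10, voxel_mm = 0.25,
                                margin_mm = 2) {
  n <- as.integer(ceiling(2 * (radius_mm + margin_mm) / voxel_mm))
  half <- n * voxel_mm / 2
  cc <- (seq_len(n) - 0.5) * voxel_mm - half
  R2 <- outer(outer(cc^2, cc^2, `+`), cc^2, `+`)
  labels <- array(0L, c(n, n, n))
  labels[R2 <= radius_mm^2] <- 1L
  voxel_phantom(labels, rep(voxel_mm, 3), list("1" = fix_water()))
}

# uniform slab of water: thickness mm along x, wide in y/z
make_slab_phantom <- function(thickness_mm, voxel_mm = 0.5,
                              width_mm = 40) {
  nx <- max(2L, as.integer(round(thickness_mm / voxel_mm)))
  nyz <- as.integer(round(width_mm / voxel_mm))
  labels <- array(1L, c(nx, nyz, nyz))
  voxel_phantom(labels, rep(voxel_mm, 3), list("1" = fix_water()))
}

# geometry with an odd pixel count so one ray passes exactly through
# the isocenter
fix_odd_geometry <- function(npix = 65, pitch = 2) {
  cbct_geometry(npix = c(npix, npix), pitch = c(pitch, pitch), angles = 0)
}

# index of the central pixel (u = v = 0) in an odd-sized detector
central_pixel <- function(geom) {
  nu <- geom$npix[1]
  c((nu + 1) / 2, (geom$npix[2] + 1) / 2)
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(max(abs(object / expected - 1)), tol)
}
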