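#' Reconstruction grid specification
#'
#' Defaults follow the full-scale reconstruction matrix of the modelled
#' cabinet (256 x 256 x 600 voxels at 0.2 mm isotropic); [desk_grid()]
#' is the small grid used throughout the test suite.
#'
#' @param dim Grid dimensions (voxels), length 3.
#' @param voxel_mm Voxel size (mm), scalar or length 3.
#' @param origin Grid-corner offset from isocenter (mm); default centers
#'   the grid.
#' @return A list with `dim`, `voxel_size`, `origin`.
#' @export
recon_grid <- function(dim = c(256, 256, 600), voxel_mm = 0.2,
                       origin = NULL) {
  voxel <- rep(voxel_mm, length.out = 3)
  if (is.null(origin)) origin <- -dim * voxel / 2
  list(dim = as.integer(dim), voxel_size = voxel, origin = origin)
}

#' @rdname recon_grid
#' @param n Voxels per side.
#' @export
desk_grid <- function(n = 64, voxel_mm = 0.4) {
  recon_grid(dim = rep(n, 3), voxel_mm = voxel_mm)
}

# row-wise ramp filtering of one projection (u along dim 1), at isocenter
# pixel scale du (mm). Returns filtered projection in 1/mm units.
.ramp_filter <- function(img, du, apodize = FALSE) {
  nu <- nrow(img)
  npad <- 2^ceiling(log2(2 * nu))
  # half ramp kernel: full-scan (2 pi) orbits count every ray twice
  n <- c(0:(npad / 2), -(npad / 2 - 1):-1)
  h <- numeric(npad)
  h[n == 0] <- 1 / (8 * du^2)
  odd <- n %% 2 != 0
  h[odd] <- -1 / (2 * pi^2 * n[odd]^2 * du^2)
  H <- Re(stats::fft(h))
  if (apodize) {
    f <- c(0:(npad / 2), (npad / 2 - 1):1) / (npad / 2)
    H <- H * 0.5 * (1 + cos(pi * f))
  }
  P <- stats::mvfft(rbind(img, matrix(0, npad - nu, ncol(img))))
  q <- Re(stats::mvfft(P * H, inverse = TRUE)) / npad
  q[seq_len(nu), , drop = FALSE] * du
}

#' FDK cone-beam reconstruction
#'
#' Standard Feldkamp--Davis--Kress filtered backprojection for a circular
#' orbit, computed in the rotating-phantom frame (so the pancake geometry
#' reduces to a conventional orbit): per-projection cosine weighting
#' `SDD / sqrt(SDD^2 + u^2 + v^2)`, row-wise ramp filtering (Ram-Lak,
#' optionally Hann-apodized, zero-padded to the next power of two,
#' Nyquist cutoff), and distance-weighted voxel-driven backprojection
#' with bilinear detector interpolation and angular weight `2*pi/N`.
#' Full-orbit scans are assumed; the two-fold ray redundancy of a 360
#' degree fan is absorbed into the filter kernel.
#'
#' @param projections A `monoct_projections` of line integrals.
#' @param grid Reconstruction grid from [recon_grid()]/[desk_grid()].
#' @param filter `"ram-lak"` or `"hann"`.
#' @return A `monoct_volume` with `values` in 1/cm.
#' @export
fdk_reconstruct <- function(projections, grid = recon_grid(),
                            filter = c("ram-lak", "hann")) {
  stopifnot(inherits(projections, "monoct_projections"))
  filter <- match.arg(filter)
  g <- projections$geometry
  ang <- projections$angles
  if (length(ang) < 2) stop("need at least 2 projection angles")
  span <- diff(range(ang))
  fan <- 2 * atan(g$npix[1] * g$pitch[1] / 2 / g$sdd) * 180 / pi
  if (span < 180 + fan - 1e-6) {
    stop(sprintf("insufficient angular coverage: %.1f deg < 180 + fan (%.1f)",
                 span, 180 + fan))
  }
  d <- dim(projections$images)
  if (!all(d[1:2] == g$npix)) stop("projection image size mismatches geometry")
  # rescale detector coordinates to the isocenter plane
  mag <- g$sad / g$sdd
  du <- g$pitch[1] * mag; dv <- g$pitch[2] * mag
  nu <- g$npix[1]; nv <- g$npix[2]
  uc <- (seq_len(nu) - (nu + 1) / 2) * du
  vc <- (seq_len(nv) - (nv + 1) / 2) * dv
  cosw <- g$sad / sqrt(g$sad^2 + outer(uc^2, vc^2, `+`))
  filt <- array(0, d)
  for (i in seq_len(d[3])) {
    filt[, , i] <- .ramp_filter(projections$images[, , i] * cosw, du,
                                apodize = (filter == "hann"))
  }
  vol <- cpp_fdk_backproject(filt, dim(filt), ang * pi / 180, g$sad,
                             du, dv, grid$dim, grid$voxel_size, grid$origin)
  # filtering grid is in mm, line integrals dimensionless -> values 1/mm
  new_volume(array(vol * 10, grid$dim), grid$voxel_size, grid$origin)
}

#' Reconstructed volume container
#'
#' @param values 3D array of attenuation values (1/cm).
#' @param voxel_size Voxel size (mm).
#' @param origin Grid-corner offset from isocenter (mm).
#' @return A `monoct_volume`.
#' @export
new_volume <- function(values, voxel_size, origin) {
  stopifnot(length(dim(values)) == 3L)
  structure(list(values = values, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "monoct_volume")
}

#' @export
print.monoct_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume> %d x %d x %d @ %.3g mm, range [%.4g, %.4g] 1/cm\n",
              d[1], d[2], d[3], x$voxel_size[1],
              min(x$values), max(x$values)))
  invisible(x)
}

#' Interpolated line profile through a volume
#'
#' Trilinear interpolation along the straight segment `from` -> `to`
#' (mm, isocenter coordinates).
#'
#' @param volume A `monoct_volume`.
#' @param from,to Segment endpoints (mm), length 3.
#' @param n Number of samples.
#' @return data.frame with `s_mm` (distance along the line) and `value`.
#' @export
central_slice_profile <- function(volume, from, to, n = 200) {
  stopifnot(inherits(volume, "monoct_volume"), length(from) == 3,
            length(to) == 3, n >= 2)
  t <- seq(0, 1, length.out = n)
  pts <- cbind(from[1] + t * (to[1] - from[1]),
               from[2] + t * (to[2] - from[2]),
               from[3] + t * (to[3] - from[3]))
  d <- dim(volume$values)
  # continuous voxel index of each sample (1-based, voxel centers)
  idx <- sweep(sweep(pts, 2, volume$origin), 2, volume$voxel_size, `/`) + 0.5
  if (any(idx < 1) || any(sweep(idx, 2, d, `>`))) {
    stop("profile line leaves the volume")
  }
  i0 <- pmin(floor(idx[, 1]), d[1] - 1); fx <- idx[, 1] - i0
  j0 <- pmin(floor(idx[, 2]), d[2] - 1); fy <- idx[, 2] - j0
  k0 <- pmin(floor(idx[, 3]), d[3] - 1); fz <- idx[, 3] - k0
  v <- volume$values
  val <- (1 - fx) * (1 - fy) * (1 - fz) * v[cbind(i0, j0, k0)] +
    fx * (1 - fy) * (1 - fz) * v[cbind(i0 + 1, j0, k0)] +
    (1 - fx) * fy * (1 - fz) * v[cbind(i0, j0 + 1, k0)] +
    fx * fy * (1 - fz) * v[cbind(i0 + 1, j0 + 1, k0)] +
    (1 - fx) * (1 - fy) * fz * v[cbind(i0, j0, k0 + 1)] +
    fx * (1 - fy) * fz * v[cbind(i0 + 1, j0, k0 + 1)] +
    (1 - fx) * fy * fz * v[cbind(i0, j0 + 1, k0 + 1)] +
    fx * fy * fz * v[cbind(i0 + 1, j0 + 1, k0 + 1)]
  data.frame(s_mm = t * sqrt(sum((to - from)^2)), value = val)
}

#' Write/read a volume as NIfTI with voxel-spacing metadata
#' @param volume A `monoct_volume`.
#' @param path Output `.nii`/`.nii.gz` path.
#' @return `read_volume` returns a `monoct_volume`.
#' @export
write_volume <- function(volume, path) {
  arr <- volume$values
  attr(arr, "pixdim") <- volume$voxel_size
  img <- RNifti::asNifti(arr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vox <- RNifti::pixdim(img)[1:3]
  new_volume(array(as.numeric(img), dim(img)[1:3]), vox,
             -dim(img)[1:3] * vox / 2)
}
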