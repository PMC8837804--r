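#' Cone-beam acquisition geometry
#'
#' Pancake convention: source and detector are stationary and the phantom
#' rotates about the vertical z axis, which is perpendicular to the
#' phantom's long (x) axis -- so the beam alternates between short lateral
#' and long longitudinal paths through the animal. Simulation is carried
#' out in the rotating-phantom frame: for projection angle `a` the source
#' sits at `-SAD * d(a)` with beam direction `d(a) = (cos a, sin a, 0)`,
#' the detector plane at `+IDD * d(a)` with rows (u) along
#' `(-sin a, cos a, 0)` and columns (v) along z. At angle 0 the beam runs
#' along the long axis (longest paths); at 90 degrees it crosses the
#' animal laterally. `conventional` mode instead puts the long axis along
#' the rotation axis (beam always lateral), for comparison.
#'
#' Distance defaults are the calibrated source/detector positions of the
#' modelled cabinet (source-isocenter 353.4 mm, isocenter-detector
#' 271.0 mm); the full panel is 176 x 128 mm^2 at 0.5 mm pitch
#' (352 x 256 pixels).
#'
#' @param sad Source-to-isocenter distance (mm).
#' @param idd Isocenter-to-detector distance (mm).
#' @param npix Detector pixels (nu, nv).
#' @param pitch Pixel pitch (du, dv) in mm.
#' @param angles Projection angles in degrees, each in `[0, 360)`.
#' @param mode `"pancake"` (default) or `"conventional"`.
#' @return A `monoct_geometry`.
#' @export
cbct_geometry <- function(sad = 353.4, idd = 271.0,
                          npix = c(352, 256), pitch = c(0.5, 0.5),
                          angles = 0:359,
                          mode = c("pancake", "conventional")) {
  mode <- match.arg(mode)
  stopifnot(sad > 0, idd > 0, all(npix > 0), all(pitch > 0),
            all(angles >= 0), all(angles < 360))
  structure(list(sad = sad, idd = idd, sdd = sad + idd,
                 npix = as.integer(npix), pitch = as.numeric(pitch),
                 angles = as.numeric(angles), mode = mode),
            class = "monoct_geometry")
}

#' Reduced detector geometry for network-scale projections
#'
#' Same source/detector distances and panel area as [cbct_geometry()]
#' but downsampled to 64 x 64 pixels: the full 176 x 128 mm^2 panel at
#' 2.75 x 2.0 mm pitch, so the field of view (and hence object
#' truncation behavior) matches the full-resolution system while the
#' image size stays divisible by the pooling depth of the desk-scale
#' network.
#'
#' @param angles Projection angles (degrees).
#' @param n Detector pixels per side.
#' @param pitch_mm Pixel pitch (mm), length 1 or 2.
#' @return A `monoct_geometry`.
#' @export
desk_geometry <- function(angles = 0:359, n = 64,
                          pitch_mm = c(2.75, 2.0)) {
  cbct_geometry(npix = c(n, n), pitch = rep(pitch_mm, length.out = 2),
                angles = angles)
}

# source position and detector pixel-center coordinates for one angle;
# returns list(src = length-3, pix = (nu*nv) x 3), all mm, phantom frame;
# offset (mm) shifts all pixel centers along the detector u/v axes
.geom_rays <- function(geometry, angle_deg, offset = c(0, 0)) {
  a <- angle_deg * pi / 180
  d <- c(cos(a), sin(a), 0)
  uhat <- c(-sin(a), cos(a), 0)
  vhat <- c(0, 0, 1)
  if (geometry$mode == "conventional") {
    # long axis along the rotation axis: swap the roles of x and z
    d <- c(0, sin(a), cos(a))
    uhat <- c(0, cos(a), -sin(a))
    vhat <- c(1, 0, 0)
  }
  src <- -geometry$sad * d
  nu <- geometry$npix[1]; nv <- geometry$npix[2]
  uc <- (seq_len(nu) - (nu + 1) / 2) * geometry$pitch[1] + offset[1]
  vc <- (seq_len(nv) - (nv + 1) / 2) * geometry$pitch[2] + offset[2]
  U <- rep(uc, times = nv); V <- rep(vc, each = nu)
  ctr <- geometry$idd * d
  pix <- cbind(ctr[1] + U * uhat[1] + V * vhat[1],
               ctr[2] + U * uhat[2] + V * vhat[2],
               ctr[3] + U * uhat[3] + V * vhat[3])
  list(src = src, pix = pix)
}
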