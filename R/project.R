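#' Per-material radiological path lengths (Siddon ray tracing)
#'
#' Traces one ray per detector pixel from the source through the voxel
#' grid and accumulates the exact intersection length per material label,
#' in cm. For a ray fully crossing the grid the per-label lengths sum to
#' the in-grid segment length; rays missing the grid return zeros.
#'
#' @param phantom A `monoct_phantom`.
#' @param geometry A `monoct_geometry`.
#' @param angle Projection angle in degrees.
#' @param offset Optional (du, dv) shift of all pixel centers along the
#'   detector axes (mm); used for aperture supersampling.
#' @return Matrix of `prod(geometry$npix)` rows (pixels, u fastest) and
#'   one column per label `0..max(label)`, lengths in cm.
#' @export
siddon_raypaths <- function(phantom, geometry, angle, offset = c(0, 0)) {
  stopifnot(inherits(phantom, "monoct_phantom"),
            inherits(geometry, "monoct_geometry"))
  rays <- .geom_rays(geometry, angle, offset)
  nlab <- max(as.integer(names(phantom$materials)))
  L <- cpp_siddon(as.integer(phantom$labels), dim(phantom$labels),
                  phantom$voxel_size, phantom$origin,
                  rays$src, rays$pix, nlab)
  colnames(L) <- as.character(0:nlab)
  L
}

# centered sub-pixel offset grid for aperture supersampling (mm)
.aperture_offsets <- function(geometry, n) {
  if (n <= 1) return(list(c(0, 0)))
  f <- ((seq_len(n) - 0.5) / n - 0.5)
  out <- list()
  for (dv in f * geometry$pitch[2]) {
    for (du in f * geometry$pitch[1]) out[[length(out) + 1]] <- c(du, dv)
  }
  out
}

#' Flood-field detector signal
#'
#' The unattenuated signal `I0 = sum_E w(E) D(E)`; identical across
#' pixels for the point source (no heel effect).
#'
#' @param spectrum A `monoct_spectrum`.
#' @param detector A `monoct_detector`.
#' @param db Attenuation table.
#' @return Scalar `I0 > 0`.
#' @export
flood_field <- function(spectrum, detector = detector_model("ideal"),
                        db = attenuation_db()) {
  stopifnot(inherits(spectrum, "monoct_spectrum"))
  i0 <- sum(spectrum$weights * detector_response(spectrum$energies, detector, db))
  if (i0 <= 0) stop("flood field is zero: spectrum carries no detectable fluence")
  i0
}

# mu matrix (nlab+1 rows incl. air) x energies for a phantom; label 0
# is treated as non-attenuating (air paths of a few cm contribute < 1e-3
# to the line integral, and flood normalization removes the constant part)
.phantom_mu <- function(phantom, energies, db) {
  nlab <- max(as.integer(names(phantom$materials)))
  mu <- matrix(0, nrow = nlab + 1, ncol = length(energies))
  for (l in seq_len(nlab)) {
    m <- phantom$materials[[as.character(l)]]
    if (!is.null(m)) mu[l + 1, ] <- material_mu(m, energies, db)
  }
  mu
}

.new_projection_set <- function(images, angles, geometry, kind,
                                meta = list()) {
  structure(list(images = images, angles = angles, geometry = geometry,
                 kind = kind, meta = meta),
            class = "monoct_projections")
}

#' Assemble a projection set from an image stack
#'
#' @param images `nu x nv x n` array of line integrals (a single matrix
#'   is promoted to one page).
#' @param angles Projection angles (degrees), length `n`.
#' @param geometry A `monoct_geometry` with matching pixel counts.
#' @param kind One of `"poly"`, `"mono"`, `"predicted-mono"`.
#' @param meta Optional metadata list.
#' @return A `monoct_projections`.
#' @export
projection_set <- function(images, angles, geometry,
                           kind = c("poly", "mono", "predicted-mono"),
                           meta = list()) {
  kind <- match.arg(kind)
  if (length(dim(images)) == 2L) images <- array(images, c(dim(images), 1))
  stopifnot(inherits(geometry, "monoct_geometry"),
            length(dim(images)) == 3L,
            dim(images)[3] == length(angles),
            all(dim(images)[1:2] == geometry$npix))
  .new_projection_set(images, angles, geometry, kind, meta)
}

#' @export
print.monoct_projections <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<projections kind=%s> %d x %d pixels, %d angle(s)\n",
              x$kind, d[1], d[2], d[3]))
  invisible(x)
}

#' Monoenergetic forward projection
#'
#' Noise-free Beer--Lambert line integrals
#' `p = sum_m mu_m(E) l_m = -ln(I/I0)` at a single energy (default
#' 35 keV, the virtual monoenergetic imaging energy, chosen just above
#' the iodine K edge).
#'
#' @param phantom A `monoct_phantom`.
#' @param geometry A `monoct_geometry`.
#' @param energy Photon energy in keV.
#' @param angles Projection angles (degrees); default from geometry.
#' @param supersample Detector-aperture subsampling factor per axis:
#'   1 (default) traces one ray per pixel center (the exact analytic
#'   contract); n > 1 averages n^2 sub-rays in the intensity domain,
#'   modelling the finite pixel aperture of an area detector (used for
#'   the training corpus, where it smooths object-boundary penumbra
#'   exactly as an area-scoring detector does).
#' @param db Attenuation table.
#' @return A `monoct_projections` (kind `"mono"`), images
#'   `nu x nv x n_angles`.
#' @export
project_mono <- function(phantom, geometry, energy = 35.0,
                         angles = geometry$angles, supersample = 1,
                         db = attenuation_db()) {
  mu <- .phantom_mu(phantom, energy, db)
  offs <- .aperture_offsets(geometry, supersample)
  imgs <- array(0, c(geometry$npix, length(angles)))
  for (i in seq_along(angles)) {
    trans <- 0
    for (off in offs) {
      L <- siddon_raypaths(phantom, geometry, angles[i], off)
      trans <- trans + exp(-(L %*% mu))
    }
    imgs[, , i] <- matrix(-log(trans / length(offs)),
                          geometry$npix[1], geometry$npix[2])
  }
  .new_projection_set(imgs, angles, geometry, "mono",
                      list(energy_keV = energy))
}

#' Polyenergetic forward projection
#'
#' Spectrally-summed primary-beam transport:
#' `I = sum_E w(E) D(E) exp(-sum_m mu_m(E) l_m)`, `p = -ln(I/I0)`.
#' Because low-energy bins are attenuated preferentially, the effective
#' attenuation `p/L` decreases with path length -- the beam-hardening
#' nonlinearity the network is trained to remove. Optional Poisson noise
#' is applied to `I` scaled to `n0` expected flood-level counts
#' (off by default; deterministic given `noise_seed`).
#'
#' @param phantom A `monoct_phantom`.
#' @param geometry A `monoct_geometry`.
#' @param spectrum A `monoct_spectrum` (e.g. [sarrp_spectrum()]).
#' @param detector A `monoct_detector`.
#' @param angles Projection angles (degrees).
#' @param n0 Optional expected photon count per pixel at flood level;
#'   `NULL` (default) disables noise.
#' @param noise_seed Seed for the Poisson draw.
#' @param supersample Detector-aperture subsampling factor per axis
#'   (see [project_mono()]).
#' @param db Attenuation table.
#' @return A `monoct_projections` (kind `"poly"`).
#' @export
project_poly <- function(phantom, geometry, spectrum = sarrp_spectrum(),
                         detector = detector_model(),
                         angles = geometry$angles,
                         n0 = NULL, noise_seed = 1L, supersample = 1,
                         db = attenuation_db()) {
  en <- spectrum$energies
  D <- detector_response(en, detector, db)
  w <- spectrum$weights * D
  i0 <- sum(w)
  if (i0 <= 0) stop("spectrum carries no detectable fluence")
  mu <- .phantom_mu(phantom, en, db)
  offs <- .aperture_offsets(geometry, supersample)
  imgs <- array(0, c(geometry$npix, length(angles)))
  n_clamped <- 0L
  for (i in seq_along(angles)) {
    I <- 0
    for (off in offs) {
      L <- siddon_raypaths(phantom, geometry, angles[i], off)
      I <- I + exp(-L %*% mu) %*% w / length(offs)
    }
    if (!is.null(n0)) {
      cnt <- with_seed(noise_seed + i - 1L,
                       stats::rpois(length(I), I / i0 * n0))
      bad <- cnt <= 0
      n_clamped <- n_clamped + sum(bad)
      cnt[bad] <- 1L  # smallest positive count
      I <- cnt / n0 * i0
    }
    imgs[, , i] <- matrix(-log(I / i0), geometry$npix[1], geometry$npix[2])
  }
  if (n_clamped > 0) {
    message("project_poly: ", n_clamped,
            " fully-absorbed pixel(s) clamped to one count")
  }
  .new_projection_set(imgs, angles, geometry, "poly",
                      list(mean_energy_keV = mean_energy(spectrum),
                           n0 = n0))
}

#' Render one polyenergetic/monoenergetic projection pair
#'
#' Materializes a `SimulationSpec` from [make_dataset()]: builds the
#' mouse or cylinder phantom, applies its augmentation, and projects the
#' identical augmented phantom at the identical angle with the 60 kVp
#' polyenergetic beam and the 35 keV monoenergetic beam. Fully
#' deterministic given the spec (bitwise-reproducible pairs).
#'
#' @param spec A `monoct_simspec`.
#' @param geometry A `monoct_geometry` (desk scale by default).
#' @param spectrum Polyenergetic spectrum.
#' @param detector Detector model.
#' @param mono_energy Monoenergetic imaging energy (keV).
#' @param supersample Detector-aperture subsampling (see
#'   [project_mono()]); the training corpus default is 2, modelling the
#'   area-scoring pixels of the reference detector.
#' @param augspec_args Extra arguments passed to [augmentation_spec()].
#' @param phantom Optional pre-built base phantom (cache for mouse specs;
#'   must match `spec$phantom_seed`).
#' @param db Attenuation table.
#' @return List with `poly` and `mono` projection sets (one angle each)
#'   and `angle`.
#' @export
simulate_pair <- function(spec, geometry = desk_geometry(),
                          spectrum = sarrp_spectrum(),
                          detector = detector_model(),
                          mono_energy = 35.0, supersample = 2,
                          augspec_args = list(),
                          phantom = NULL, db = attenuation_db()) {
  stopifnot(inherits(spec, "monoct_simspec"))
  if (is.null(phantom)) phantom <- base_phantom(spec)
  aspec <- do.call(augmentation_spec,
                   c(list(seed = spec$aug_seed), augspec_args))
  aug <- augment(phantom, aspec)
  poly <- project_poly(aug$phantom, geometry, spectrum, detector,
                       angles = aug$angle, supersample = supersample,
                       db = db)
  mono <- project_mono(aug$phantom, geometry, mono_energy,
                       angles = aug$angle, supersample = supersample,
                       db = db)
  poly$meta$spec <- mono$meta$spec <- spec
  list(poly = poly, mono = mono, angle = aug$angle)
}

#' Base (un-augmented) phantom of a simulation spec
#'
#' Mouse specs map to [make_mouse_phantom()] with the spec's phantom
#' seed; cylinder specs sample diameter (5-20 mm), length (20-50 mm),
#' orientation, off-center position and tissue from the tissue library.
#'
#' @param spec A `monoct_simspec`.
#' @return A `monoct_phantom`.
#' @export
base_phantom <- function(spec) {
  if (spec$kind == "mouse") {
    make_mouse_phantom(spec$phantom_seed,
                       head_lift_mm = (spec$phantom_id %% 3 == 0) * 4,
                       water_tube = spec$phantom_id %% 4 == 0)
  } else {
    with_seed(spec$phantom_seed, {
      d <- stats::runif(1, 5, 20)
      len <- stats::runif(1, 20, 50)
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      tis <- sample(tissue_names(), 1)
      vox <- rep(0.23, 3)
      ext <- abs(u) * len / 2 + d / 2 * sqrt(pmax(0, 1 - u^2))
      ctr <- stats::runif(3, -8, 8)
      dims <- as.integer(ceiling(2 * (ext + abs(ctr) + 1) / vox))
      make_cylinder_phantom(d, len, material_library()[[tis]], u, ctr,
                            dim = dims, voxel_size = vox)
    })
  }
}

#' Render a dataset of projection pairs into arrays
#'
#' Runs [simulate_pair()] for every spec, reusing base mouse phantoms
#' across their augmented pairs. Returns stacked arrays directly
#' consumable by the network.
#'
#' @param specs List of `monoct_simspec` from [make_dataset()].
#' @param geometry,spectrum,detector,mono_energy,supersample,db See
#'   [simulate_pair()].
#' @param augspec_args Augmentation options for every pair.
#' @param verbose Print progress every 25 pairs.
#' @return List with `poly` and `mono` (`nu x nv x n` arrays), `angles`,
#'   `geometry`, and `specs`.
#' @export
render_dataset <- function(specs, geometry = desk_geometry(),
                           spectrum = sarrp_spectrum(),
                           detector = detector_model(),
                           mono_energy = 35.0, supersample = 2,
                           augspec_args = list(),
                           db = attenuation_db(), verbose = FALSE) {
  n <- length(specs)
  poly <- array(0, c(geometry$npix, n))
  mono <- array(0, c(geometry$npix, n))
  angles <- numeric(n)
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    sp <- specs[[i]]
    ph <- NULL
    if (sp$kind == "mouse") {
      key <- as.character(sp$phantom_seed)
      if (is.null(cache[[key]])) cache[[key]] <- base_phantom(sp)
      ph <- cache[[key]]
    }
    pair <- simulate_pair(sp, geometry, spectrum, detector, mono_energy,
                          supersample, augspec_args, phantom = ph, db = db)
    poly[, , i] <- pair$poly$images[, , 1]
    mono[, , i] <- pair$mono$images[, , 1]
    angles[i] <- pair$angle
    if (verbose && i %% 25 == 0) message("rendered ", i, "/", n, " pairs")
  }
  list(poly = poly, mono = mono, angles = angles, geometry = geometry,
       specs = specs)
}

#' Write/read a projection set (multi-page 32-bit TIFF + text sidecar)
#'
#' One 32-bit page per angle. TIFF samples are stored min/max-normalized
#' (32-bit quantization, relative resolution ~2e-10); the affine
#' `value = vmin + sample * (vmax - vmin)` is recorded in the YAML
#' sidecar (`<path>.geometry.yaml`) together with distances, pitch,
#' angles, kind and provenance. The reader applies the affine and
#' validates that sidecar and stack agree.
#'
#' @param pset A `monoct_projections`.
#' @param path Output `.tif` path.
#' @return `read_projections` returns a `monoct_projections`.
#' @export
write_projections <- function(pset, path) {
  stopifnot(inherits(pset, "monoct_projections"))
  vmin <- min(pset$images); vmax <- max(pset$images)
  span <- if (vmax > vmin) vmax - vmin else 1
  pages <- lapply(seq_along(pset$angles),
                  function(i) (pset$images[, , i] - vmin) / span)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  g <- pset$geometry
  yaml::write_yaml(list(kind = pset$kind, sad = g$sad, idd = g$idd,
                        npix = g$npix, pitch = g$pitch, mode = g$mode,
                        vmin = vmin, vmax = vmax,
                        angles = pset$angles,
                        meta = pset$meta[setdiff(names(pset$meta), "spec")]),
                   paste0(path, ".geometry.yaml"))
  invisible(path)
}

#' @rdname write_projections
#' @export
read_projections <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  side <- yaml::read_yaml(paste0(path, ".geometry.yaml"))
  g <- cbct_geometry(sad = side$sad, idd = side$idd, npix = side$npix,
                     pitch = side$pitch, angles = side$angles,
                     mode = side$mode)
  if (length(pages) != length(side$angles)) {
    stop("sidecar/stack mismatch in ", path, ": ", length(pages),
         " pages vs ", length(side$angles), " angles")
  }
  if (!all(dim(pages[[1]]) == side$npix)) {
    stop("sidecar/stack pixel-count mismatch in ", path)
  }
  span <- if (side$vmax > side$vmin) side$vmax - side$vmin else 1
  imgs <- side$vmin + array(unlist(pages), c(side$npix, length(pages))) * span
  .new_projection_set(imgs, side$angles, g, side$kind, side$meta)
}
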