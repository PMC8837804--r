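#' Voxelized phantom
#'
#' A labeled 3D grid plus a material table. Label 0 is always air; every
#' other label present in the grid must have an entry in `materials`
#' (names are the label integers as strings). The grid lives in world
#' coordinates (mm) with the phantom's long axis along x and the rotation
#' axis of the pancake geometry along z; `origin` is the position of the
#' grid corner (outer edge of the first voxel) relative to the isocenter.
#'
#' @param labels 3D integer array of material labels.
#' @param voxel_size Numeric length-3, (dx, dy, dz) in mm; anisotropy allowed.
#' @param materials Named list mapping label (as character) to
#'   [material()]; `"0"` (air) is added automatically if missing.
#' @param origin Numeric length-3 (mm); default centers the grid on the
#'   isocenter.
#' @return A `monoct_phantom`.
#' @export
voxel_phantom <- function(labels, voxel_size, materials, origin = NULL) {
  stopifnot(length(dim(labels)) == 3L, length(voxel_size) == 3L,
            all(voxel_size > 0))
  if (is.null(origin)) origin <- -dim(labels) * voxel_size / 2
  if (!("0" %in% names(materials))) {
    materials[["0"]] <- material_library()$air
  }
  present <- sort(unique(as.integer(labels)))
  missing <- setdiff(as.character(present), names(materials))
  if (length(missing) > 0) {
    stop("labels without material entry: ", paste(missing, collapse = ", "))
  }
  structure(list(labels = labels,
                 voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin),
                 materials = materials),
            class = "monoct_phantom")
}

#' @export
print.monoct_phantom <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<phantom> %d x %d x %d voxels @ %.3g x %.3g x %.3g mm, %d materials\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2],
              x$voxel_size[3], length(x$materials)))
  invisible(x)
}

# voxel-center world coordinates along one axis
.vox_centers <- function(n, h, o) o + (seq_len(n) - 0.5) * h

#' Mathematical cylinder phantom
#'
#' Voxel centers are classified by an exact point-in-cylinder test against
#' an arbitrarily oriented finite cylinder.
#'
#' @param diameter,length Cylinder dimensions in mm.
#' @param mat Cylinder material ([material()]).
#' @param orientation Axis direction (length-3, normalized internally).
#' @param center Cylinder center in mm relative to isocenter.
#' @param dim Grid dimensions (voxels).
#' @param voxel_size Voxel size in mm (length 3).
#' @return A `monoct_phantom` with labels 1 (cylinder) and 0 (air).
#' @export
make_cylinder_phantom <- function(diameter, length, mat,
                                  orientation = c(1, 0, 0),
                                  center = c(0, 0, 0),
                                  dim = c(128, 96, 96),
                                  voxel_size = c(0.23, 0.23, 0.23)) {
  stopifnot(diameter > 0, length > 0)
  u <- orientation / sqrt(sum(orientation^2))
  r <- diameter / 2
  # world-axis half-extent of the tilted cylinder
  half_ext <- abs(u) * length / 2 + r * sqrt(pmax(0, 1 - u^2))
  grid_half <- dim * voxel_size / 2
  if (any(abs(center) + half_ext > grid_half + 1e-9)) {
    stop("cylinder exceeds the voxel grid (extent ",
         paste(sprintf("%.1f", abs(center) + half_ext), collapse = "/"),
         " mm vs grid half-size ",
         paste(sprintf("%.1f", grid_half), collapse = "/"), " mm)")
  }
  origin <- -grid_half
  cx <- .vox_centers(dim[1], voxel_size[1], origin[1]) - center[1]
  cy <- .vox_centers(dim[2], voxel_size[2], origin[2]) - center[2]
  cz <- .vox_centers(dim[3], voxel_size[3], origin[3]) - center[3]
  X <- array(cx, dim); Y <- array(rep(cy, each = dim[1]), dim)
  Z <- array(rep(cz, each = dim[1] * dim[2]), dim)
  ax <- X * u[1] + Y * u[2] + Z * u[3]
  rad2 <- X^2 + Y^2 + Z^2 - ax^2
  inside <- abs(ax) <= length / 2 & rad2 <= r^2
  if (!any(inside)) {
    stop("degenerate cylinder: no voxel center falls inside (diameter ",
         diameter, " mm vs voxel ", max(voxel_size), " mm)")
  }
  labels <- array(0L, dim)
  labels[inside] <- 1L
  voxel_phantom(labels, voxel_size, materials = list("1" = mat), origin = origin)
}

# evaluate code with a private, restored RNG stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Procedural mouse-like phantom
#'
#' Builds an elongated mouse-like body from parametrized ellipsoids and
#' tubes: soft-tissue body with skin shell, head with brain and skull,
#' a connected spine, paired lungs, heart, liver, kidneys, intestine and
#' a ventral fat depot -- at least 10 distinct tissue labels drawn from the
#' reference tissue library. Options mimic common imaging situations: a
#' head lifted out of the body axis (anesthesia nose cone) and a
#' water-filled tube attached below the animal (uniformity insert).
#' Deterministic given `seed`.
#'
#' @param seed Integer seed controlling all sampled anatomy.
#' @param body_length_mm,body_width_mm Length-2 sampling ranges (mm).
#' @param voxel_mm Nominal isotropic voxel size of the generated grid (mm).
#' @param head_lift_mm Vertical (z) displacement of the head region; 0
#'   keeps the head on the body axis.
#' @param water_tube Logical; attach a water cylinder below the body.
#' @return A `monoct_phantom`.
#' @export
make_mouse_phantom <- function(seed,
                               body_length_mm = c(55, 75),
                               body_width_mm = c(22, 28),
                               voxel_mm = 0.23,
                               head_lift_mm = 0,
                               water_tube = FALSE) {
  stopifnot(length(body_length_mm) == 2, diff(body_length_mm) >= 0,
            length(body_width_mm) == 2, diff(body_width_mm) >= 0,
            voxel_mm > 0)
  with_seed(seed, {
    L <- stats::runif(1, body_length_mm[1], body_length_mm[2])
    W <- stats::runif(1, body_width_mm[1], body_width_mm[2])
    H <- W * stats::runif(1, 0.80, 0.95)
    head_l <- 0.32 * L * stats::runif(1, 0.9, 1.1)   # head half-length scale
    jit <- function(s) stats::runif(1, 1 - s, 1 + s)

    head_cx <- L / 2 + 0.55 * head_l
    tube_r <- 4.5
    x_lo <- -L / 2 - 3; x_hi <- head_cx + head_l * 0.75 + 3
    y_half <- W / 2 + 3
    z_lo <- -H / 2 - (if (water_tube) 2 * tube_r + 3 else 3)
    z_hi <- max(H / 2, abs(head_lift_mm) + 0.30 * H) + 4

    nd <- as.integer(ceiling(c(x_hi - x_lo, 2 * y_half, z_hi - z_lo) / voxel_mm))
    origin <- c(x_lo, -y_half, z_lo)
    cx <- .vox_centers(nd[1], voxel_mm, origin[1])
    cy <- .vox_centers(nd[2], voxel_mm, origin[2])
    cz <- .vox_centers(nd[3], voxel_mm, origin[3])

    # ellipsoid membership evaluated on its bounding sub-grid only
    ell <- function(c0, a) {
      ii <- which(abs(cx - c0[1]) <= a[1])
      jj <- which(abs(cy - c0[2]) <= a[2])
      kk <- which(abs(cz - c0[3]) <= a[3])
      m <- outer(outer(((cx[ii] - c0[1]) / a[1])^2,
                       ((cy[jj] - c0[2]) / a[2])^2, `+`),
                 ((cz[kk] - c0[3]) / a[3])^2, `+`) <= 1
      list(i = ii, j = jj, k = kk, m = m)
    }
    set_lab <- function(labels, e, value) {
      sub <- labels[e$i, e$j, e$k, drop = FALSE]
      sub[e$m] <- value
      labels[e$i, e$j, e$k] <- sub
      labels
    }

    lib <- material_library()
    lab <- c(soft_tissue = 1L, skin = 2L, cortical_bone = 3L, brain = 4L,
             lung = 5L, heart = 6L, liver = 7L, kidney = 8L,
             intestine = 9L, adipose = 10L, water = 11L, spongiosa = 12L)
    labels <- array(0L, nd)

    labels <- set_lab(labels, ell(c(0, 0, 0), c(L / 2, W / 2, H / 2)),
                      lab[["skin"]])
    labels <- set_lab(labels, ell(c(0, 0, 0), 0.93 * c(L / 2, W / 2, H / 2)),
                      lab[["soft_tissue"]])

    # head: ellipsoid, optionally lifted along z (nose-cone posture)
    hz <- head_lift_mm
    labels <- set_lab(labels, ell(c(head_cx, 0, hz),
                                  c(head_l, 0.36 * W, 0.36 * H)),
                      lab[["skin"]])
    labels <- set_lab(labels, ell(c(head_cx, 0, hz),
                                  0.90 * c(head_l, 0.36 * W, 0.36 * H)),
                      lab[["soft_tissue"]])
    skull_c <- c(head_cx, 0, hz + 0.05 * H)
    skull_a <- c(0.62 * head_l, 0.26 * W, 0.26 * H)
    labels <- set_lab(labels, ell(skull_c, skull_a), lab[["cortical_bone"]])

    # spine: trabecular-bone tube along x, ramping up to the (possibly
    # lifted) skull base; spongiosa rather than cortical bone, so axial
    # rays see realistic vertebral attenuation instead of a solid
    # cortical rod
    zs0 <- 0.22 * H
    ramp_x0 <- 0.35 * L
    r_sp <- max(1.1, 2.4 * voxel_mm)
    ii <- which(cx >= -0.47 * L & cx <= head_cx)
    jj <- which(abs(cy) <= r_sp)
    zrng <- range(zs0, hz + 0.05 * H)
    kk <- which(cz >= zrng[1] - r_sp & cz <= zrng[2] + r_sp)
    t <- pmin(1, pmax(0, (cx[ii] - ramp_x0) /
                           (head_cx - 0.3 * head_l - ramp_x0)))
    z_sp <- zs0 + t^2 * (hz + 0.05 * H - zs0)
    # y^2 + (z - z_sp(x))^2 <= r^2, evaluated on the sub-grid
    sp_m <- array(FALSE, c(length(ii), length(jj), length(kk)))
    for (k in seq_along(kk)) {
      dz2 <- (cz[kk[k]] - z_sp)^2                     # along ii
      sp_m[, , k] <- outer(dz2, cy[jj]^2, `+`) <= r_sp^2
    }
    sub <- labels[ii, jj, kk, drop = FALSE]
    sub[sp_m & sub != lab[["brain"]]] <- lab[["spongiosa"]]
    labels[ii, jj, kk] <- sub

    labels <- set_lab(labels, ell(skull_c, 0.80 * skull_a), lab[["brain"]])

    # thorax and abdomen organs (jittered per seed)
    lung_a <- c(0.14 * L, 0.14 * W, 0.22 * H) * jit(0.1)
    for (s in c(-1, 1)) {
      labels <- set_lab(labels,
                        ell(c(0.22 * L, s * 0.16 * W, 0.02 * H) * jit(0.05),
                            lung_a), lab[["lung"]])
    }
    labels <- set_lab(labels, ell(c(0.18 * L * jit(0.08), 0, -0.08 * H),
                                  c(0.07, 0.10, 0.12) * W), lab[["heart"]])
    labels <- set_lab(labels, ell(c(0.02 * L * jit(0.3), 0.03 * W, -0.10 * H),
                                  c(0.11 * L, 0.28 * W, 0.22 * H) * jit(0.08)),
                      lab[["liver"]])
    for (s in c(-1, 1)) {
      labels <- set_lab(labels,
                        ell(c(-0.12 * L * jit(0.1), s * 0.17 * W, 0.08 * H),
                            c(0.045 * L, 0.09 * W, 0.10 * H)), lab[["kidney"]])
    }
    labels <- set_lab(labels, ell(c(-0.26 * L * jit(0.08), 0, -0.08 * H),
                                  c(0.12 * L, 0.26 * W, 0.20 * H) * jit(0.1)),
                      lab[["intestine"]])
    labels <- set_lab(labels, ell(c(-0.30 * L, 0, -0.30 * H),
                                  c(0.10 * L, 0.22 * W, 0.10 * H)),
                      lab[["adipose"]])

    if (water_tube) {
      zt <- -H / 2 - tube_r - 1.5
      ii <- which(abs(cx) <= 0.35 * L)
      jj <- which(abs(cy) <= tube_r)
      kk <- which(abs(cz - zt) <= tube_r)
      tb <- outer(cy[jj]^2, (cz[kk] - zt)^2, `+`) <= tube_r^2
      sub <- labels[ii, jj, kk, drop = FALSE]
      sub[rep(tb, each = length(ii))] <- lab[["water"]]
      labels[ii, jj, kk] <- sub
    }

    mats <- stats::setNames(lapply(names(lab), function(nm) lib[[nm]]),
                            as.character(lab))
    voxel_phantom(labels, rep(voxel_mm, 3), mats, origin = origin)
  })
}

#' Label the connected components of a voxel mask
#'
#' 6-connectivity flood fill; QA helper used e.g. to verify that the
#' procedural skeleton forms one connected component.
#'
#' @param mask 3D logical (or 0/1) array.
#' @return Integer array of the same shape: 0 outside the mask, component
#'   id (1-based, decreasing size order) inside.
#' @export
label_components <- function(mask) {
  stopifnot(length(dim(mask)) == 3L)
  out <- cpp_label_components(array(as.integer(mask != 0), dim(mask)))
  array(out, dim(mask))
}

#' Write/read a phantom (NIfTI label volume + material sidecar)
#'
#' The label grid is written as a NIfTI volume with voxel-spacing
#' metadata; materials go to a plain-text sidecar `<path>.materials.tsv`
#' (columns: label, name, density, composition as `El:frac` pairs).
#'
#' @param phantom A `monoct_phantom`.
#' @param path Output path (`.nii` / `.nii.gz`).
#' @return `read_phantom` returns a `monoct_phantom`.
#' @export
write_phantom <- function(phantom, path) {
  arr <- phantom$labels
  attr(arr, "pixdim") <- phantom$voxel_size
  img <- RNifti::asNifti(arr, datatype = "int16")
  RNifti::writeNifti(img, path)
  side <- paste0(path, ".materials.tsv")
  rows <- vapply(names(phantom$materials), function(l) {
    m <- phantom$materials[[l]]
    comp <- paste(sprintf("%s:%.6f", names(m$composition), m$composition),
                  collapse = ",")
    sprintf("%s\t%s\t%.6g\t%s", l, m$name, m$density, comp)
  }, character(1))
  writeLines(c("label\tname\tdensity_g_cm3\tcomposition", rows,
               sprintf("# origin_mm\t%s", paste(phantom$origin, collapse = ","))),
             side)
  invisible(path)
}

#' @rdname write_phantom
#' @param path Path written by `write_phantom`.
#' @export
read_phantom <- function(path) {
  img <- RNifti::readNifti(path)
  vox <- RNifti::pixdim(img)[1:3]
  side <- readLines(paste0(path, ".materials.tsv"))
  origin_line <- grep("^# origin_mm", side, value = TRUE)
  origin <- as.numeric(strsplit(strsplit(origin_line, "\t")[[1]][2], ",")[[1]])
  body <- side[!grepl("^#", side)][-1]
  mats <- list()
  for (r in body) {
    f <- strsplit(r, "\t")[[1]]
    parts <- strsplit(strsplit(f[4], ",")[[1]], ":")
    comp <- stats::setNames(vapply(parts, function(p) as.numeric(p[2]), 0),
                            vapply(parts, `[`, "", 1))
    mats[[f[1]]] <- material(f[2], comp, as.numeric(f[3]))
  }
  voxel_phantom(array(as.integer(img), dim(img)[1:3]), vox, mats, origin)
}
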