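#' Dataset augmentation specification
#'
#' Randomization applied to each simulated projection pair: per-axis
#' anisotropic voxel size, 3D phantom translation, projection angle,
#' independent per-element composition perturbation and density
#' perturbation. All samples are drawn uniformly within the closed
#' ranges; an all-zero spec is the identity (angle 0).
#'
#' @param voxel_range Closed voxel-size sampling range per axis (mm).
#' @param translation_mm Half-range of the per-axis translation (mm).
#' @param angle_range Closed integer range of projection angles (degrees).
#' @param rel_comp,rel_density Relative half-ranges of the elemental and
#'   density perturbations (0.05 = +/-5%).
#' @param seed Integer seed; fully determines the draw.
#' @return A `monoct_augspec`.
#' @export
augmentation_spec <- function(voxel_range = c(0.17, 0.29),
                              translation_mm = 10,
                              angle_range = c(0, 359),
                              rel_comp = 0.05, rel_density = 0.05,
                              seed = 1L) {
  stopifnot(length(voxel_range) == 2, voxel_range[1] > 0,
            voxel_range[2] >= voxel_range[1], translation_mm >= 0,
            angle_range[1] >= 0, angle_range[2] < 360,
            rel_comp >= 0, rel_comp < 1, rel_density >= 0, rel_density < 1)
  structure(list(voxel_range = voxel_range, translation_mm = translation_mm,
                 angle_range = angle_range, rel_comp = rel_comp,
                 rel_density = rel_density, seed = as.integer(seed)),
            class = "monoct_augspec")
}

#' Apply a randomized augmentation to a phantom
#'
#' Samples a new anisotropic voxel size (rescaling the phantom about the
#' isocenter), a translation, a projection angle, and perturbs every
#' non-air material's composition (independent relative factor per
#' element, then renormalization to unit sum) and density. Deterministic
#' given `spec$seed`.
#'
#' @param phantom A `monoct_phantom`.
#' @param spec An [augmentation_spec()].
#' @return List with elements `phantom` (augmented) and `angle` (degrees).
#' @export
augment <- function(phantom, spec) {
  stopifnot(inherits(phantom, "monoct_phantom"), inherits(spec, "monoct_augspec"))
  with_seed(spec$seed, {
    vox <- stats::runif(3, spec$voxel_range[1], spec$voxel_range[2])
    shift <- stats::runif(3, -spec$translation_mm, spec$translation_mm)
    angle <- sample(seq(spec$angle_range[1], spec$angle_range[2]), 1)
    # rescale about the isocenter: origin scales with the voxel size
    scale <- vox / phantom$voxel_size
    origin <- phantom$origin * scale + shift
    mats <- lapply(names(phantom$materials), function(l) {
      m <- phantom$materials[[l]]
      if (l == "0") m else perturb_material(m, spec$rel_comp, spec$rel_density)
    })
    names(mats) <- names(phantom$materials)
    list(phantom = voxel_phantom(phantom$labels, vox, mats, origin),
         angle = angle)
  })
}

#' Build the simulation corpus specification
#'
#' Enumerates one `SimulationSpec` per projection pair: `n_mouse` mouse
#' phantoms with `pairs_per_mouse` augmented pairs each, plus
#' `n_cylinder` randomized cylinder pairs. The default counts reproduce
#' the study corpus: 9 x 105 + 945 = 1890 pairs. Every spec carries its
#' own derived seeds, so pairs are independently renderable and the whole
#' corpus is reproducible from `seed`.
#'
#' @param n_mouse Number of distinct mouse phantoms.
#' @param pairs_per_mouse Augmented projection pairs per mouse phantom.
#' @param n_cylinder Number of cylinder projection pairs.
#' @param seed Master seed.
#' @return List of `monoct_simspec` objects, length
#'   `n_mouse * pairs_per_mouse + n_cylinder`.
#' @export
make_dataset <- function(n_mouse = 9, pairs_per_mouse = 105,
                         n_cylinder = 945, seed = 1L) {
  stopifnot(n_mouse >= 0, pairs_per_mouse >= 0, n_cylinder >= 0)
  n <- n_mouse * pairs_per_mouse + n_cylinder
  with_seed(seed, {
    mouse_seeds <- sample.int(.Machine$integer.max, max(n_mouse, 1))
    pair_seeds <- sample.int(.Machine$integer.max, max(n, 1))
    specs <- vector("list", n)
    i <- 0L
    for (m in seq_len(n_mouse)) {
      for (p in seq_len(pairs_per_mouse)) {
        i <- i + 1L
        specs[[i]] <- structure(
          list(id = i, kind = "mouse", phantom_id = m,
               phantom_seed = mouse_seeds[m], aug_seed = pair_seeds[i]),
          class = "monoct_simspec")
      }
    }
    for (p in seq_len(n_cylinder)) {
      i <- i + 1L
      specs[[i]] <- structure(
        list(id = i, kind = "cylinder", phantom_id = NA_integer_,
             phantom_seed = pair_seeds[i], aug_seed = pair_seeds[i]),
        class = "monoct_simspec")
    }
    specs
  })
}
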