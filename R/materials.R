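#' Define a material by elemental composition and density
#'
#' @param name Material name.
#' @param composition Named numeric vector of elemental mass fractions
#'   (element symbols as names). Normalized to sum exactly to 1.
#' @param density Mass density in g/cm^3 (> 0).
#' @return A `monoct_material`.
#' @export
material <- function(name, composition, density) {
  if (length(composition) == 0L) stop("empty composition for material '", name, "'")
  stopifnot(is.numeric(composition), !is.null(names(composition)),
            all(composition >= 0), sum(composition) > 0)
  if (!is.numeric(density) || density <= 0) {
    stop("density must be > 0 (got ", density, ")")
  }
  structure(list(name = name,
                 composition = composition / sum(composition),
                 density = as.numeric(density)),
            class = "monoct_material")
}

#' @export
print.monoct_material <- function(x, ...) {
  cat(sprintf("<material %s> density %.4g g/cm3\n", x$name, x$density))
  comp <- paste(sprintf("%s:%.4f", names(x$composition), x$composition),
                collapse = " ")
  cat(" ", comp, "\n")
  invisible(x)
}

#' Linear attenuation coefficient of a material
#'
#' Mixture rule: `mu(E) = rho * sum_i w_i * (mu/rho)_i(E)` over the
#' material's elemental mass fractions.
#'
#' @param mat A `monoct_material`.
#' @param energies Energies in keV.
#' @param db Attenuation table.
#' @return Numeric vector of mu in 1/cm, one per energy.
#' @export
material_mu <- function(mat, energies, db = attenuation_db()) {
  stopifnot(inherits(mat, "monoct_material"))
  if (length(mat$composition) == 0L) stop("material has empty composition")
  mu_rho <- numeric(length(energies))
  for (el in names(mat$composition)) {
    mu_rho <- mu_rho + mat$composition[[el]] * elemental_mu_rho(el, energies, db)
  }
  mat$density * mu_rho
}

#' Reference material library
#'
#' Tissues with ICRU-style reference compositions (15 tissue entries
#' spanning soft tissue, bone, parenchymal organs, fat, skin, ...) plus
#' filter/detector materials (Be, Al, C, CsI). Loaded from the plain-text
#' table `inst/extdata/materials.tsv`.
#'
#' @return Named list of `monoct_material` objects.
#' @export
material_library <- function() {
  if (is.null(.monoct_cache$mat_lib)) {
    path <- system.file("extdata", "materials.tsv", package = "monoct",
                        mustWork = TRUE)
    d <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
    lib <- lapply(seq_len(nrow(d)), function(i) {
      parts <- strsplit(strsplit(d$composition[i], ",")[[1]], ":")
      comp <- vapply(parts, function(p) as.numeric(p[2]), numeric(1))
      names(comp) <- vapply(parts, `[`, character(1), 1)
      material(d$name[i], comp, d$density_g_cm3[i])
    })
    names(lib) <- d$name
    .monoct_cache$mat_lib <- lib
  }
  .monoct_cache$mat_lib
}

#' Names of the tissue subset of the material library
#' @return Character vector of the 15 tissue names (air excluded).
#' @export
tissue_names <- function() {
  c("water", "soft_tissue", "muscle", "adipose", "skin", "cortical_bone",
    "spongiosa", "brain", "lung", "liver", "kidney", "heart", "blood",
    "cartilage", "intestine")
}

#' Randomly perturb a material's composition and density
#'
#' Each elemental mass fraction is multiplied by an independent factor
#' drawn uniformly from `1 +/- rel_comp`, then the fractions are
#' renormalized to sum to 1; the density is scaled by an independent
#' factor from `1 +/- rel_density`. Used by the dataset augmentation.
#'
#' @param mat A `monoct_material`.
#' @param rel_comp,rel_density Relative half-ranges (e.g. 0.05 for +/-5%).
#' @return Perturbed `monoct_material`.
#' @export
perturb_material <- function(mat, rel_comp = 0.05, rel_density = 0.05) {
  comp <- mat$composition *
    stats::runif(length(mat$composition), 1 - rel_comp, 1 + rel_comp)
  rho <- mat$density * stats::runif(1, 1 - rel_density, 1 + rel_density)
  material(mat$name, comp, rho)
}
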