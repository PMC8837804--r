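#' Embedded elemental mass-attenuation database
#'
#' Loads the package's elemental mass-attenuation table (total attenuation
#' with coherent scatter, `cm^2/g`, 5--80 keV). Absorption edges are stored
#' as duplicated energy rows: the first row of a duplicated pair belongs to
#' the below-edge branch, the second to the above-edge branch. The table is
#' plain TSV under `inst/extdata/mu_rho_elements.tsv` (columns: element
#' symbol, Z, atomic mass, energy in keV, mu/rho in cm^2/g).
#'
#' @return A data.frame with columns `element`, `Z`, `A`, `energy_keV`,
#'   `mu_rho`, sorted by element then energy.
#' @export
attenuation_db <- function() {
  if (is.null(.monoct_cache$att_db)) {
    path <- system.file("extdata", "mu_rho_elements.tsv", package = "monoct",
                        mustWork = TRUE)
    db <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                            stringsAsFactors = FALSE)
    .monoct_cache$att_db <- db
  }
  .monoct_cache$att_db
}

.monoct_cache <- new.env(parent = emptyenv())

#' Elemental mass-attenuation coefficients
#'
#' Log-log interpolation of the embedded per-element tables. Queries that
#' fall exactly on a duplicated edge energy take the above-edge branch, so
#' e.g. `elemental_mu_rho("I", 33.2)` returns the K-shell-ionizing value.
#'
#' @param element Element symbol (e.g. `"O"`, `"I"`).
#' @param energies Numeric vector of photon energies in keV.
#' @param db Attenuation table as returned by [attenuation_db()].
#' @return Numeric vector of mu/rho in cm^2/g, one per energy.
#' @export
elemental_mu_rho <- function(element, energies, db = attenuation_db()) {
  stopifnot(is.character(element), length(element) == 1L)
  tab <- db[db$element == element, , drop = FALSE]
  if (nrow(tab) == 0L) {
    stop("unknown element: '", element, "' (not in the embedded attenuation table)")
  }
  e_tab <- tab$energy_keV
  v_tab <- tab$mu_rho
  rng <- range(e_tab)
  if (any(energies < rng[1] | energies > rng[2])) {
    stop(sprintf("energy out of table range [%g, %g] keV for element %s",
                 rng[1], rng[2], element))
  }
  # findInterval with duplicated edge abscissae resolves a query exactly at
  # the edge to the above-edge branch (last matching index).
  idx <- findInterval(energies, e_tab, all.inside = TRUE)
  e0 <- e_tab[idx]; e1 <- e_tab[idx + 1L]
  v0 <- v_tab[idx]; v1 <- v_tab[idx + 1L]
  out <- ifelse(
    e1 == e0,
    v1,
    exp(log(v0) + (log(energies) - log(e0)) / (log(e1) - log(e0)) *
          (log(v1) - log(v0)))
  )
  as.numeric(out)
}
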