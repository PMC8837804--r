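#' Default photon energy grid
#'
#' 1 keV sampling from 5 to 60 keV (bin-center convention). The lower edge
#' matches the low-energy cutoff below which photons are not tracked; the
#' upper edge is the tube-potential endpoint of a 60 kVp beam.
#'
#' @param from,to,by Grid limits and spacing in keV.
#' @return Strictly increasing numeric vector of energies in keV.
#' @export
energy_grid <- function(from = 5, to = 60, by = 1) {
  stopifnot(from > 0, to > from, by > 0)
  seq(from, to, by = by)
}

new_spectrum <- function(energies, weights) {
  stopifnot(length(energies) == length(weights),
            all(energies > 0), !is.unsorted(energies, strictly = TRUE),
            all(weights >= 0), any(weights > 0))
  structure(list(energies = as.numeric(energies),
                 weights = as.numeric(weights)),
            class = "monoct_spectrum")
}

#' Unfiltered bremsstrahlung (Kramers) tube spectrum
#'
#' Relative photon fluence per bin proportional to `max(0, kvp/E - 1)`:
#' the thick-target bremsstrahlung law. Characteristic tungsten K lines are
#' not excited below 69 kVp, so at 60 kVp filtered bremsstrahlung alone is
#' an adequate tube model; anode-angle and heel effects are ignored.
#'
#' @param kvp Tube potential in kV (spectrum endpoint in keV).
#' @param grid Energy grid in keV, see [energy_grid()].
#' @return A `monoct_spectrum`.
#' @export
kramers_spectrum <- function(kvp, grid = energy_grid()) {
  if (kvp <= min(grid)) {
    stop("kvp (", kvp, " keV) must exceed the lowest grid energy (",
         min(grid), " keV)")
  }
  w <- pmax(0, kvp / grid - 1)
  new_spectrum(grid, w / sum(w))
}

#' Attenuate a spectrum by absorber layers
#'
#' Per-bin Beer--Lambert attenuation `exp(-sum(mu_layer(E) * t_layer))`.
#' Models inherent (Be window) and added (Al) tube filtration; hardens a
#' polyenergetic beam (mean energy strictly increases for any absorbing
#' layer of positive thickness).
#'
#' @param spectrum A `monoct_spectrum`.
#' @param layers List of `list(material =, thickness_cm =)` pairs.
#' @param db Attenuation table.
#' @return Filtered `monoct_spectrum` (weights renormalized not).
#' @export
filter_spectrum <- function(spectrum, layers, db = attenuation_db()) {
  stopifnot(inherits(spectrum, "monoct_spectrum"))
  w <- spectrum$weights
  for (layer in layers) {
    t_cm <- layer$thickness_cm
    if (t_cm < 0) stop("negative layer thickness: ", t_cm, " cm")
    if (t_cm == 0) next
    mu <- material_mu(layer$material, spectrum$energies, db)
    w <- w * exp(-mu * t_cm)
  }
  new_spectrum(spectrum$energies, w)
}

#' Monoenergetic spectrum
#'
#' A single bin of weight 1 exactly at the requested energy; used as the
#' virtual monoenergetic imaging beam (default use: 35 keV, just above the
#' iodine K edge at 33.2 keV).
#'
#' @param energy Photon energy in keV; must lie inside the attenuation
#'   table range so that projections through any material are defined.
#' @param db Attenuation table used for the range check.
#' @return A `monoct_spectrum` with one bin.
#' @export
mono_spectrum <- function(energy, db = attenuation_db()) {
  rng <- range(db$energy_keV)
  if (energy < rng[1] || energy > rng[2]) {
    stop(sprintf("energy %g keV outside table range [%g, %g]",
                 energy, rng[1], rng[2]))
  }
  new_spectrum(energy, 1.0)
}

#' Fluence-weighted mean energy of a spectrum
#' @param spectrum A `monoct_spectrum`.
#' @return Mean energy in keV.
#' @export
mean_energy <- function(spectrum) {
  stopifnot(inherits(spectrum, "monoct_spectrum"))
  sum(spectrum$energies * spectrum$weights) / sum(spectrum$weights)
}

#' The default 60 kVp imaging spectrum
#'
#' Kramers bremsstrahlung filtered by 0.8 mm beryllium (inherent) and
#' 1.0 mm aluminum (added spectral filtration), the recommended imaging
#' configuration of the small-animal irradiation cabinet being modelled.
#'
#' @param kvp Tube potential (kV).
#' @param grid Energy grid.
#' @param be_mm,al_mm Filtration thicknesses in mm.
#' @return A `monoct_spectrum`.
#' @export
sarrp_spectrum <- function(kvp = 60, grid = energy_grid(),
                           be_mm = 0.8, al_mm = 1.0) {
  lib <- material_library()
  filter_spectrum(
    kramers_spectrum(kvp, grid),
    list(list(material = lib$beryllium, thickness_cm = be_mm / 10),
         list(material = lib$aluminum, thickness_cm = al_mm / 10))
  )
}

#' Read/write a spectrum as two-column text (energy keV, relative fluence)
#' @param spectrum A `monoct_spectrum`.
#' @param path File path.
#' @return `read_spectrum` returns a `monoct_spectrum`; `write_spectrum`
#'   returns `path` invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  utils::write.table(
    data.frame(energy_keV = spectrum$energies, fluence = spectrum$weights),
    path, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  new_spectrum(d[[1]], d[[2]])
}
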