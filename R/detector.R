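#' Flat-panel detector response model
#'
#' Three response modes:
#' \describe{
#'   \item{`ideal`}{photon counting, `D(E) = 1`.}
#'   \item{`energy-integrating`}{`D(E) = E` (keV): signal proportional to
#'     deposited energy, full absorption.}
#'   \item{`csi`}{energy integrating behind a protective carbon entrance
#'     plate with absorption in a CsI scintillator:
#'     `D(E) = E * exp(-mu_C(E) t_plate) * (1 - exp(-mu_CsI(E) t_scint))`.
#'     The default thicknesses (1 mm carbon, 600 um CsI) follow the
#'     flat-panel stack of the modelled cabinet; glass substrate and
#'     aluminum backing sit behind the scintillator and do not attenuate
#'     the detected signal.}
#' }
#' Whether the real panel scores deposited energy or photon counts is not
#' observable from outside; energy integration with CsI absorption is the
#' conventional indirect flat-panel assumption and is the package default,
#' with the ideal modes retained for analytic tests.
#'
#' @param mode One of `"ideal"`, `"energy-integrating"`, `"csi"`.
#' @param scint_um CsI scintillator thickness in micrometres.
#' @param plate_mm Carbon entrance plate thickness in millimetres.
#' @return A `monoct_detector`.
#' @export
detector_model <- function(mode = c("csi", "energy-integrating", "ideal"),
                           scint_um = 600, plate_mm = 1.0) {
  mode <- match.arg(mode)
  structure(list(mode = mode, scint_um = scint_um, plate_mm = plate_mm),
            class = "monoct_detector")
}

#' Energy-dependent detector response weights D(E)
#'
#' @param energies Energies in keV.
#' @param model A `monoct_detector`.
#' @param db Attenuation table.
#' @return Non-negative numeric vector, one weight per energy.
#' @export
detector_response <- function(energies, model = detector_model(),
                              db = attenuation_db()) {
  stopifnot(inherits(model, "monoct_detector"))
  lib <- material_library()
  switch(model$mode,
    "ideal" = rep(1.0, length(energies)),
    "energy-integrating" = as.numeric(energies),
    "csi" = {
      mu_c <- material_mu(lib$carbon, energies, db)
      mu_csi <- material_mu(lib$csi, energies, db)
      as.numeric(energies) *
        exp(-mu_c * model$plate_mm / 10) *
        (1 - exp(-mu_csi * model$scint_um / 1e4))
    },
    stop("unknown detector mode: ", model$mode)
  )
}
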