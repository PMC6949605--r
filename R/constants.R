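# Physical constants (CODATA 2018, exact where the SI redefinition makes them so).
# Kept in one place so every photon-budget number is bit-reproducible.

.const <- list(
  e_charge      = 1.602176634e-19,    # C (exact)
  avogadro      = 6.02214076e23,      # mol^-1 (exact)
  k_boltzmann   = 1.380649e-23,       # J K^-1 (exact)
  r_e_cm        = 2.8179403262e-13,   # classical electron radius, cm
  hc_keV_A      = 12.398419843320026, # h*c, keV * Angstrom
  mec2_keV      = 510.99895000,       # electron rest energy, keV
  atm_Pa        = 101325,             # standard atmosphere, Pa
  barn_cm2      = 1e-24
)

#' Photon wavelength from energy
#'
#' @param energy_kev photon energy in keV.
#' @return wavelength in Angstrom.
#' @keywords internal
wavelength_A <- function(energy_kev) {
  stopifnot(energy_kev > 0)
  .const$hc_keV_A / energy_kev
}
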