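# Atomic scattering cross-sections for the photon-budget model.
#
# Elastic (Rayleigh) scattering is computed by integrating the Thomson
# differential cross-section weighted by the squared atomic form factor;
# inelastic (Compton) scattering by integrating the Klein-Nishina
# differential cross-section weighted by an incoherent scattering function.
# Form factors use the standard International Tables 4-Gaussian
# (Cromer-Mann) parametrisation, f(s) = sum_i a_i exp(-b_i s^2) + c with
# s = sin(theta/2)/lambda in 1/Angstrom, embedded below for Z = 1..20.

# columns: a1..a4, b1..b4, c
.it92 <- local({
  m <- matrix(c(
    0.493002, 0.322912, 0.140191, 0.040810, 10.510900, 26.125700,  3.142360,  57.799700,  0.003038,
    0.873400, 0.630900, 0.311200, 0.178000,  9.103700,  3.356800, 22.927600,   0.982100,  0.006400,
    1.128200, 0.750800, 0.617500, 0.465300,  3.954600,  1.052400, 85.390500, 168.261000,  0.037700,
    1.591900, 1.127800, 0.539100, 0.702900, 43.642700,  1.862300, 103.483000,  0.542000,  0.038500,
    2.054500, 1.332600, 1.097900, 0.706800, 23.218500,  1.021000, 60.349800,   0.140300, -0.193200,
    2.310000, 1.020000, 1.588600, 0.865000, 20.843900, 10.207500,  0.568700,  51.651200,  0.215600,
   12.212600, 3.132200, 2.012500, 1.166300,  0.005700,  9.893300, 28.997500,   0.582600, -11.529000,
    3.048500, 2.286800, 1.546300, 0.867000, 13.277100,  5.701100,  0.323900,  32.908900,  0.250800,
    3.539200, 2.641200, 1.517000, 1.024300, 10.282500,  4.294400,  0.261500,  26.147600,  0.277600,
    3.955300, 3.112500, 1.454600, 1.125100,  8.404200,  3.426200,  0.230600,  21.718400,  0.351500,
    4.762600, 3.173600, 1.267400, 1.112800,  3.285000,  8.842200,  0.313600, 129.424000,  0.676000,
    5.420400, 2.173500, 1.226900, 2.307300,  2.827500, 79.261100,  0.380800,   7.193700,  0.858400,
    6.420200, 1.900200, 1.593600, 1.964600,  3.038700,  0.742600, 31.547200,  85.088600,  1.115100,
    6.291500, 3.035300, 1.989100, 1.541000,  2.438600, 32.333700,  0.678500,  81.693700,  1.140700,
    6.434500, 4.179100, 1.780000, 1.490800,  1.906700, 27.157000,  0.526000,  68.164500,  1.114900,
    6.905300, 5.203400, 1.437900, 1.586300,  1.467900, 22.215100,  0.253600,  56.172000,  0.866900,
   11.460400, 7.196400, 6.255600, 1.645500,  0.010400,  1.166200, 18.519400,  47.778400, -9.557400,
    7.484500, 6.772300, 0.653900, 1.644200,  0.907200, 14.840700, 43.898300,  33.392900,  1.444500,
    8.218600, 7.439800, 1.051900, 0.865900, 12.794900,  0.774800, 213.187000,  41.684100,  1.422800,
    8.626600, 7.387300, 1.589900, 1.021100, 10.442100,  0.659900, 85.748400,  178.437000,  1.375100
  ), ncol = 9, byrow = TRUE)
  rownames(m) <- c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
                   "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca")
  m
})

.atomic_number <- stats::setNames(seq_len(nrow(.it92)), rownames(.it92))

#' Atomic form factor
#'
#' Coherent X-ray scattering factor of a neutral atom in the Cromer-Mann
#' parametrisation.
#'
#' @param element element symbol (e.g. `"O"`); Z = 1..20 supported.
#' @param s momentum-transfer coordinate `sin(theta/2)/lambda` in 1/Angstrom,
#'   where `theta` is the scattering angle.
#' @return dimensionless form factor (electrons), vectorised over `s`.
#' @export
atomic_form_factor <- function(element, s) {
  cf <- .it92_row(element)
  f <- rep(cf[9], length(s))
  s2 <- s * s
  for (i in 1:4) f <- f + cf[i] * exp(-cf[i + 4] * s2)
  f
}

.it92_row <- function(element) {
  if (!element %in% rownames(.it92)) {
    stop("unknown element symbol: '", element,
         "' (supported: ", paste(rownames(.it92), collapse = ", "), ")")
  }
  .it92[element, ]
}

#' Atomic Rayleigh (coherent) scattering cross-section
#'
#' Integrates the Thomson differential cross-section weighted by the squared
#' atomic form factor over the full solid angle:
#' `sigma = 2 pi r_e^2 int (1 + cos^2 t)/2 f(s)^2 sin t dt`.
#'
#' @inheritParams atomic_form_factor
#' @param energy_kev photon energy in keV.
#' @return cross-section in cm^2 per atom.
#' @export
sigma_rayleigh_atomic <- function(element, energy_kev) {
  stopifnot(energy_kev > 0)
  lam <- wavelength_A(energy_kev)
  integrand <- function(theta) {
    s <- sin(theta / 2) / lam
    f <- atomic_form_factor(element, s)
    (1 + cos(theta)^2) / 2 * f * f * sin(theta)
  }
  v <- stats::integrate(integrand, 0, pi, rel.tol = 1e-10, subdivisions = 500L)
  2 * pi * .const$r_e_cm^2 * v$value
}

# Klein-Nishina differential cross-section per electron, cm^2/sr.
.kn_dcs <- function(energy_kev, theta) {
  k <- energy_kev / .const$mec2_keV
  ratio <- 1 / (1 + k * (1 - cos(theta)))   # E'/E
  0.5 * .const$r_e_cm^2 * ratio^2 * (ratio + 1 / ratio - sin(theta)^2)
}

#' Atomic Compton (incoherent) scattering cross-section
#'
#' Klein-Nishina differential cross-section weighted by an incoherent
#' scattering function in the Waller-Hartree closure approximation
#' `S(s, Z) = Z (1 - (f(s)/Z)^2)`, which is exact for hydrogen and an upper
#' bound for heavier atoms. Adequate for the few-percent role Compton plays
#' in a soft X-ray photon budget; not a precision Compton model.
#'
#' @inheritParams sigma_rayleigh_atomic
#' @return cross-section in cm^2 per atom.
#' @export
sigma_compton_atomic <- function(element, energy_kev) {
  stopifnot(energy_kev > 0)
  .it92_row(element)  # validates symbol
  z <- .atomic_number[[element]]
  lam <- wavelength_A(energy_kev)
  integrand <- function(theta) {
    s <- sin(theta / 2) / lam
    f <- atomic_form_factor(element, s)
    S <- z * (1 - (f / z)^2)
    .kn_dcs(energy_kev, theta) * S * sin(theta)
  }
  v <- stats::integrate(integrand, 0, pi, rel.tol = 1e-10, subdivisions = 500L)
  2 * pi * v$value
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Scattering cross-section of one scattering unit
#'
#' Cross-section per molecule/monomer/atom for a given composition under one
#' of three conventions:
#' \describe{
#'   \item{`atomic_additive`}{independent-atom coherent (Rayleigh) sum,
#'     `sum_i n_i sigma_R(Z_i, E)`. The default: it is the convention used by
#'     standard X-ray cross-section compilations for compounds.}
#'   \item{`atomic_plus_incoherent`}{adds the independent-atom Compton term.}
#'   \item{`molecular`}{coherent scattering of the whole unit in the
#'     forward-interference (point-molecule) limit, `|sum_i n_i f_i(s)|^2`
#'     under the Thomson kernel. An upper bound: real intramolecular
#'     interference lies between this and `atomic_additive`.}
#' }
#'
#' @param composition named integer vector of stoichiometric counts, e.g.
#'   `c(H = 2, O = 1)`.
#' @param energy_kev photon energy in keV.
#' @param mode cross-section convention, see Details.
#' @return cross-section in cm^2 per scattering unit.
#' @examples
#' rayleigh_cross_section(c(H = 2, O = 1), 7.5) / 1e-24  # barn per molecule
#' @export
rayleigh_cross_section <- function(composition, energy_kev,
                                   mode = c("atomic_additive",
                                            "atomic_plus_incoherent",
                                            "molecular")) {
  mode <- match.arg(mode)
  stopifnot(length(composition) >= 1, all(composition > 0))
  els <- names(composition)
  if (is.null(els) || any(!nzchar(els))) {
    stop("composition must be a named vector of element counts")
  }
  for (el in els) .it92_row(el)  # validate symbols up front
  if (mode == "molecular") {
    lam <- wavelength_A(energy_kev)
    integrand <- function(theta) {
      s <- sin(theta / 2) / lam
      F <- 0
      for (i in seq_along(composition)) {
        F <- F + composition[[i]] * atomic_form_factor(els[i], s)
      }
      (1 + cos(theta)^2) / 2 * F * F * sin(theta)
    }
    v <- stats::integrate(integrand, 0, pi, rel.tol = 1e-10,
                          subdivisions = 500L)
    return(2 * pi * .const$r_e_cm^2 * v$value)
  }
  sig <- 0
  for (i in seq_along(composition)) {
    sig <- sig + composition[[i]] * sigma_rayleigh_atomic(els[i], energy_kev)
    if (mode == "atomic_plus_incoherent") {
      sig <- sig + composition[[i]] * sigma_compton_atomic(els[i], energy_kev)
    }
  }
  sig
}
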