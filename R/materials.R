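# Materials: the layers of a fixed-target sample enclosure, described by one
# scattering unit (molecule, monomer or atom) plus enough information to turn
# a path length into an areal number density of those units.

#' Define an enclosure material
#'
#' A material is one layer of the beam path: a solid or liquid slab, a
#' 2-D sheet (e.g. a graphene monolayer), or a gas column. Exactly the
#' parameters required by the chosen `phase` must be supplied; they determine
#' the areal number density of scattering units seen by the beam.
#'
#' @param name label used in reports.
#' @param composition named integer vector of element counts per scattering
#'   unit, e.g. `c(C = 5, H = 8, O = 2)` for a PMMA monomer.
#' @param phase one of `"solid"`, `"liquid"`, `"sheet"`, `"gas"`.
#' @param mass_density g/cm^3 (solid/liquid).
#' @param molar_mass g/mol per scattering unit (solid/liquid). If omitted it
#'   is computed from the composition and standard atomic weights.
#' @param thickness_cm beam path length in cm (solid/liquid/gas). See
#'   [thickness_cm()] for unit helpers.
#' @param areal_density_per_layer scattering units per cm^2 in one layer
#'   (sheet phase).
#' @param n_layers number of stacked sheets (sheet phase).
#' @param temperature_k gas temperature in K.
#' @param pressure_pa gas partial pressure in Pa.
#' @return an object of class `sfx_material`.
#' @examples
#' material("water", c(H = 2, O = 1), "liquid",
#'          mass_density = 0.997, thickness_cm = 1e-4)
#' @export
material <- function(name, composition,
                     phase = c("solid", "liquid", "sheet", "gas"),
                     mass_density = NULL, molar_mass = NULL,
                     thickness_cm = NULL,
                     areal_density_per_layer = NULL, n_layers = 1L,
                     temperature_k = NULL, pressure_pa = NULL) {
  phase <- match.arg(phase)
  stopifnot(length(composition) >= 1, all(composition > 0))
  if (phase %in% c("solid", "liquid")) {
    if (is.null(mass_density) || is.null(thickness_cm)) {
      stop("phase '", phase, "' requires mass_density and thickness_cm")
    }
    stopifnot(mass_density > 0, thickness_cm >= 0)
    if (is.null(molar_mass)) molar_mass <- molar_mass_of(composition)
    stopifnot(molar_mass > 0)
  } else if (phase == "sheet") {
    if (is.null(areal_density_per_layer)) {
      stop("phase 'sheet' requires areal_density_per_layer")
    }
    stopifnot(areal_density_per_layer >= 0, n_layers >= 1)
  } else {
    if (is.null(temperature_k) || is.null(pressure_pa) ||
        is.null(thickness_cm)) {
      stop("phase 'gas' requires temperature_k, pressure_pa and thickness_cm")
    }
    stopifnot(temperature_k > 0, pressure_pa >= 0, thickness_cm >= 0)
  }
  structure(
    list(name = name, composition = composition, phase = phase,
         mass_density = mass_density, molar_mass = molar_mass,
         thickness_cm = thickness_cm,
         areal_density_per_layer = areal_density_per_layer,
         n_layers = as.integer(n_layers),
         temperature_k = temperature_k, pressure_pa = pressure_pa),
    class = "sfx_material")
}

#' @export
print.sfx_material <- function(x, ...) {
  comp <- paste0(names(x$composition), x$composition, collapse = "")
  cat(sprintf("<sfx_material> %s [%s] %s\n", x$name, x$phase, comp))
  cat(sprintf("  areal number density: %.4g cm^-2\n", areal_number_density(x)))
  invisible(x)
}

# Standard atomic weights (g/mol), 2021 IUPAC abridged values.
.atomic_weight <- c(H = 1.008, He = 4.0026, Li = 6.94, Be = 9.0122,
                    B = 10.81, C = 12.011, N = 14.007, O = 15.999,
                    F = 18.998, Ne = 20.180, Na = 22.990, Mg = 24.305,
                    Al = 26.982, Si = 28.085, P = 30.974, S = 32.06,
                    Cl = 35.45, Ar = 39.948, K = 39.098, Ca = 40.078)

#' Molar mass of a composition
#' @param composition named integer vector of element counts.
#' @return g/mol per scattering unit.
#' @export
molar_mass_of <- function(composition) {
  els <- names(composition)
  unknown <- setdiff(els, names(.atomic_weight))
  if (length(unknown)) stop("unknown element symbol: ", unknown[1])
  sum(.atomic_weight[els] * as.numeric(composition))
}

#' Convert a thickness to cm
#' @param value numeric thickness.
#' @param unit one of `"cm"`, `"mm"`, `"um"`, `"nm"`.
#' @return thickness in cm.
#' @export
thickness_cm <- function(value, unit = c("cm", "mm", "um", "nm")) {
  unit <- match.arg(unit)
  value * switch(unit, cm = 1, mm = 0.1, um = 1e-4, nm = 1e-7)
}

#' Areal number density of scattering units
#'
#' The number of scattering units per cm^2 of beam footprint:
#' `rho N_A t / M` for condensed slabs, per-layer density times layer count
#' for sheets, and `(P / k_B T) t` for ideal-gas columns.
#'
#' @param mat an [material()] object.
#' @return scattering units per cm^2.
#' @export
areal_number_density <- function(mat) {
  stopifnot(inherits(mat, "sfx_material"))
  switch(mat$phase,
    solid = ,
    liquid = mat$mass_density * .const$avogadro * mat$thickness_cm /
             mat$molar_mass,
    sheet = mat$areal_density_per_layer * mat$n_layers,
    gas = mat$pressure_pa / (.const$k_boltzmann * mat$temperature_k) *
          1e-6 * mat$thickness_cm  # m^-3 -> cm^-3, times path in cm
  )
}

# Graphene: 2 carbon atoms per hexagonal cell of lattice constant a = 2.46 A.
.graphene_areal <- function(a_angstrom = 2.46) {
  cell_cm2 <- sqrt(3) / 2 * (a_angstrom * 1e-8)^2
  2 / cell_cm2
}

#' Saturation vapor pressure of water
#'
#' Antoine equation with the classical 1-100 degC coefficients
#' (A = 8.07131, B = 1730.63, C = 233.426; pressure in mmHg, temperature
#' in degC), converted to Pa.
#'
#' @param temperature_k temperature in K.
#' @return saturation pressure in Pa.
#' @export
water_saturation_pressure <- function(temperature_k) {
  t_c <- temperature_k - 273.15
  stopifnot(t_c > 0, t_c <= 100)
  p_mmhg <- 10^(8.07131 - 1730.63 / (233.426 + t_c))
  p_mmhg * 101325 / 760
}

#' Built-in material library
#'
#' Ready-made materials for the standard components of a graphene/polymer
#' sandwich target and its environment. Thicknesses default to the values
#' used in our worked examples and can be overridden.
#'
#' @param name one of `"water"`, `"pmma"`, `"mylar"`, `"kapton"`,
#'   `"graphene"`, `"helium"`, `"water_vapor"`.
#' @param thickness_cm path length in cm (ignored for graphene).
#' @param n_layers number of graphene monolayers.
#' @param temperature_k gas temperature in K.
#' @param relative_humidity fraction (0-1) for water vapor; partial pressure
#'   is `RH * P_sat(T)`.
#' @param pressure_pa gas pressure in Pa for helium.
#' @return an [material()] object.
#' @details Densities: water 0.997 g/cm^3; PMMA monomer C5H8O2, 1.18 g/cm^3;
#' Mylar/PET monomer C10H8O4, 1.38 g/cm^3; Kapton monomer C22H10N2O5,
#' 1.42 g/cm^3. Graphene is a sheet of 3.816e15 C atoms cm^-2 per monolayer
#' (2 atoms per hexagonal cell, a = 2.46 A).
#' @export
material_library <- function(name, thickness_cm = NULL, n_layers = 1L,
                             temperature_k = 293.15,
                             relative_humidity = 1.0,
                             pressure_pa = .const$atm_Pa) {
  switch(name,
    water = material("water", c(H = 2, O = 1), "liquid",
                     mass_density = 0.997, molar_mass = 18.015,
                     thickness_cm = thickness_cm %||% 1e-4),
    pmma = material("PMMA", c(C = 5, H = 8, O = 2), "solid",
                    mass_density = 1.18,
                    thickness_cm = thickness_cm %||% 80e-7),
    mylar = material("Mylar", c(C = 10, H = 8, O = 4), "solid",
                     mass_density = 1.38,
                     thickness_cm = thickness_cm %||% 5e-4),
    kapton = material("Kapton", c(C = 22, H = 10, N = 2, O = 5), "solid",
                      mass_density = 1.42,
                      thickness_cm = thickness_cm %||% 125e-4),
    graphene = material("graphene", c(C = 1), "sheet",
                        areal_density_per_layer = .graphene_areal(),
                        n_layers = n_layers),
    helium = material("He", c(He = 1), "gas",
                      temperature_k = temperature_k,
                      pressure_pa = pressure_pa,
                      thickness_cm = thickness_cm %||% 1),
    water_vapor = material("water vapor", c(H = 2, O = 1), "gas",
                           temperature_k = temperature_k,
                           pressure_pa = relative_humidity *
                             water_saturation_pressure(temperature_k),
                           thickness_cm = thickness_cm %||% 1),
    stop("unknown library material: '", name, "'")
  )
}
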