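# Photon-budget model: incident photon counts, areal densities,
# cross-sections and the N_scat budget.

test_that("photons_per_pulse follows the closed form", {
  expect_identical(photons_per_pulse(0, 7.5), 0)
  # E(J) / (E_photon in J), computed independently
  expect_equal(photons_per_pulse(1, 7.5),
               1e-3 / (7.5e3 * 1.602176634e-19), tolerance = 1e-12)
  expect_equal(photons_per_pulse(1, 7.5), 8.322012e11, tolerance = 1e-6)
  expect_equal(photons_per_pulse(1, 9.5), 6.570010e11, tolerance = 1e-6)
  # linear in pulse energy
  expect_equal(photons_per_pulse(3.7, 9.5), 3.7 * photons_per_pulse(1, 9.5))
  expect_error(photons_per_pulse(1, 0), "positive")
  expect_error(photons_per_pulse(1, -2), "positive")
})

test_that("areal number density covers the three phase conventions", {
  w0 <- material("water", c(H = 2, O = 1), "liquid", mass_density = 0.997,
                 molar_mass = 18.015, thickness_cm = 0)
  expect_identical(areal_number_density(w0), 0)
  w1 <- material_library("water", thickness_cm = 1e-4)
  # rho N_A t / M for a 1 um water film
  expect_equal(areal_number_density(w1),
               0.997 * 6.02214076e23 * 1e-4 / 18.015, tolerance = 1e-12)
  expect_equal(areal_number_density(w1), 3.3328e18, tolerance = 1e-4)
  # graphene monolayer: 2 atoms per hexagonal cell, a = 2.46 A
  g1 <- material_library("graphene", n_layers = 1)
  expect_equal(areal_number_density(g1),
               2 / (sqrt(3) / 2 * (2.46e-8)^2), tolerance = 1e-12)
  expect_equal(areal_number_density(g1), 3.82e15, tolerance = 2e-3)
  g8 <- material_library("graphene", n_layers = 8)
  expect_equal(areal_number_density(g8), 8 * areal_number_density(g1))
  # ideal-gas column: P / (k_B T) * t
  he <- material_library("helium", thickness_cm = 1)
  expect_equal(areal_number_density(he),
               101325 / (1.380649e-23 * 293.15) * 1e-6, tolerance = 1e-12)
  expect_error(material("x", c(C = 1), "liquid", thickness_cm = 1),
               "requires")
  expect_error(material("x", c(C = 1), "gas", thickness_cm = 1),
               "requires")
})

test_that("water saturation pressure matches the reference value at 20 C", {
  # steam-table value at 20 C is 2339 Pa
  expect_equal(water_saturation_pressure(293.15), 2339, tolerance = 0.005)
})

test_that("atomic cross-sections agree with an independent integration", {
  # Frozen oracle: same International Tables coefficients integrated with
  # an independent implementation (Python/scipy adaptive quadrature).
  coh <- list(H = c(0.0881, 0.0587), He = c(0.6179, 0.4269),
              C = c(4.5023, 3.4302), N = c(6.7705, 5.0361),
              O = c(9.9625, 7.2960))
  inc <- list(H = c(0.5589, 0.5833), He = c(0.9876, 1.0722),
              C = c(3.1391, 3.2885), N = c(3.5710, 3.7837),
              O = c(3.9432, 4.2351))
  for (el in names(coh)) {
    for (i in 1:2) {
      e <- c(7.5, 9.5)[i]
      expect_equal(sigma_rayleigh_atomic(el, e) / barn, coh[[el]][i],
                   tolerance = 0.01, label = paste("coh", el, e))
      expect_equal(sigma_compton_atomic(el, e) / barn, inc[[el]][i],
                   tolerance = 0.01, label = paste("inc", el, e))
    }
  }
})

test_that("coherent cross-sections decrease with energy over 5-12 keV", {
  for (el in c("H", "C", "N", "O")) {
    s <- vapply(c(5, 7.5, 9.5, 12), sigma_rayleigh_atomic, numeric(1),
                element = el)
    expect_true(all(diff(s) < 0), label = el)
  }
})

test_that("rayleigh_cross_section modes behave as documented", {
  # additivity of the independent-atom mode is exact
  expect_equal(rayleigh_cross_section(c(C = 2), 7.5),
               2 * sigma_rayleigh_atomic("C", 7.5), tolerance = 1e-12)
  s_add <- rayleigh_cross_section(c(H = 2, O = 1), 7.5)
  expect_equal(s_add,
               2 * sigma_rayleigh_atomic("H", 7.5) +
                 sigma_rayleigh_atomic("O", 7.5), tolerance = 1e-12)
  # incoherent mode adds a positive Compton term
  s_inc <- rayleigh_cross_section(c(H = 2, O = 1), 7.5,
                                  mode = "atomic_plus_incoherent")
  expect_gt(s_inc, s_add)
  # point-molecule mode exceeds the additive mode (in-phase interference)
  s_mol <- rayleigh_cross_section(c(H = 2, O = 1), 7.5, mode = "molecular")
  expect_gt(s_mol, s_add)
  expect_error(rayleigh_cross_section(c(Xx = 1), 7.5), "unknown element")
  expect_error(rayleigh_cross_section(c(H = 2, O = 1), 7.5, mode = "bogus"))
})

test_that("n_scat is linear in thickness and pulse energy, zero at zero", {
  beam <- beam_spec(7.5, 1)
  w0 <- material("water", c(H = 2, O = 1), "liquid", mass_density = 0.997,
                 molar_mass = 18.015, thickness_cm = 0)
  expect_identical(n_scat(w0, beam)$total_scattered_photons, 0)
  w1 <- material_library("water", thickness_cm = 1e-4)
  w2 <- material_library("water", thickness_cm = 2e-4)
  expect_equal(n_scat(w2, beam)$total_scattered_photons,
               2 * n_scat(w1, beam)$total_scattered_photons,
               tolerance = 1e-12)
  b2 <- beam_spec(7.5, 2.5)
  expect_equal(n_scat(w1, b2)$total_scattered_photons,
               2.5 * n_scat(w1, beam)$total_scattered_photons,
               tolerance = 1e-12)
})

test_that("n_scat is invariant under the beam area", {
  w <- material_library("water", thickness_cm = 1e-4)
  vals <- vapply(c(1e-10, 1e-8, 1e-2, 17.3), function(a) {
    n_scat(w, beam_spec(7.5, 1, beam_area_cm2 = a))$total_scattered_photons
  }, numeric(1))
  expect_true(all(vals == vals[1]))
})

test_that("background_budget orders components and flags the dominant one", {
  stack <- list(material_library("graphene", n_layers = 8),
                material_library("pmma"),
                material_library("water", thickness_cm = 20e-4))
  b <- background_budget(stack, beam_spec(7.5, 1))
  expect_equal(attr(b, "dominant"), "water")
  expect_true(b$dominant[1] && b$material[1] == "water")
  expect_true(all(diff(b$scattered_photons) <= 0))
  expect_equal(attr(b, "total"), sum(b$scattered_photons))
  # enclosure-only stack total = graphene + PMMA components
  encl <- background_budget(stack[1:2], beam_spec(7.5, 1))
  expect_equal(attr(encl, "total"),
               sum(b$scattered_photons[b$material != "water"]),
               tolerance = 1e-12)
})

test_that("cross-section mode calibration prefers the additive convention", {
  cal <- calibrate_cross_section_mode()
  expect_equal(attr(cal, "best_mode"), "atomic_additive")
  expect_true(all(c("material", "mode", "ratio") %in% names(cal)))
  # carbon-film components reproduce reference values closely under the
  # additive mode; the liquid-water and helium reference rows do not (a
  # documented inconsistency of the reference set, see the vignette)
  add <- cal[cal$mode == "atomic_additive", ]
  carbon <- add$material %in% c("graphene", "PMMA", "Mylar")
  expect_true(all(abs(add$ratio[carbon] - 1) < 0.15))
})

test_that("material stacks round-trip through the YAML config", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "- name: water",
    "  phase: liquid",
    "  composition: {H: 2, O: 1}",
    "  mass_density: 0.997",
    "  thickness_um: 20",
    "- name: graphene",
    "  phase: sheet",
    "  composition: {C: 1}",
    "  areal_density_per_layer: 3.8162e15",
    "  n_layers: 8"), path)
  stack <- read_stack(path)
  expect_length(stack, 2)
  expect_equal(stack[[1]]$thickness_cm, 20e-4)
  expect_equal(areal_number_density(stack[[2]]), 8 * 3.8162e15)
})
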