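# Shared fixtures, built in code. Detector geometries for tests keep the
# full q coverage of the default 512-pixel panel by scaling the pixel pitch
# with the panel size, so the water ring at 2 1/Angstrom stays on-panel.

test_geometry <- function(n = 128L, energy_kev = 7.5) {
  detector_geometry(n_fast = n, n_slow = n, pixel_um = 110 * 512 / n,
                    distance_mm = 27, photon_energy_kev = energy_kev)
}

test_layout <- function(n_window_rows = 4L, n_window_cols = 8L) {
  make_chip_layout("custom", n_window_rows = n_window_rows,
                   n_window_cols = n_window_cols, window_mm = c(1.5, 1.5),
                   strut_um = 100, pore_um = 15, spacing_um = 50)
}

# flat low-occupancy scene for gain calibration runs
cal_scene <- function(median_pp = 0.3) {
  scene(median_pp = median_pp, occupancy_lambda = 0,
        ring_weight = 0.5, flat_weight = 1)
}

barn <- 1e-24
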