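# Radial profiles, medians, population classification, hit finding.

test_that("radial average of a uniform frame is flat and normalises linearly", {
  geom <- test_geometry(64)
  f <- matrix(3.7, 64, 64)
  rp <- radial_average(f, geom, n_bins = 20)
  expect_equal(rp$mean_intensity[rp$n_pixels > 0],
               rep(3.7, sum(rp$n_pixels > 0)), tolerance = 1e-12)
  rp2 <- radial_average(f, geom, n_bins = 20, pulse_energy_mj = 2)
  expect_equal(rp2$mean_intensity, rp$mean_intensity / 2, tolerance = 1e-12)
  expect_true(all(diff(rp$q_center) > 0))
  expect_lte(sum(rp$n_pixels), 64 * 64)
  expect_error(radial_average(matrix(0, 10, 10), geom), "shape")
  bad <- detector_geometry(64, 64, beam_center = c(-5, 32))
  expect_error(radial_average(f, bad), "outside")
})

test_that("median intensity is robust to saturated-pixel injection", {
  f <- matrix(20, 64, 64)
  expect_equal(median_intensity(f, 1), 20)
  expect_equal(median_intensity(f, 2), 10)
  g <- f
  g[sample.int(length(g), round(0.005 * length(g)))] <- 1e4
  expect_equal(median_intensity(g, 1), 20)
  # 1% perturbation moves the median by far less than 1%
  h <- f + matrix(stats::rnorm(64 * 64, 0, 0.5), 64)
  h2 <- h
  h2[sample.int(length(h2), round(0.01 * length(h2)))] <- 1e4
  expect_lt(abs(median_intensity(h2, 1) / median_intensity(h, 1) - 1), 0.01)
  expect_error(median_intensity(f, 1, mask = matrix(FALSE, 64, 64)),
               "no valid pixels")
})

test_that("population classification partitions the axis at the fixed thresholds", {
  expect_equal(as.character(classify_shot(c(3, 45, 7, 20, 37))),
               c("low", "high", "unclassified", "moderate", "unclassified"))
  # boundary semantics: < 5 low, [10, 35] moderate, > 40 high
  expect_equal(as.character(classify_shot(c(5, 10, 35, 40))),
               c("unclassified", "moderate", "moderate", "unclassified"))
  x <- seq(0, 60, by = 0.25)
  pop <- classify_shot(x)
  expect_false(any(is.na(pop)))  # total partition, no overlaps
  expect_true(all(x[pop == "low"] < 5))
  expect_true(all(x[pop == "moderate"] >= 10 & x[pop == "moderate"] <= 35))
  expect_true(all(x[pop == "high"] > 40))
  expect_error(classify_shot(-1), "non-negative")
})

test_that("find_hits counts injected disk peaks and applies thresholds", {
  f <- matrix(10, 128, 128)
  set.seed(3)
  pos <- cbind(sample(seq(6, 122, by = 10), 12),
               sample(seq(6, 122, by = 10), 12))
  for (k in 1:12) f[pos[k, 1] + (-1:1), pos[k, 2] + (-1:1)] <- 500
  r <- find_hits(f, hit_params())
  expect_equal(r$n_peaks, 12)
  expect_true(r$is_hit)
  expect_true(all(r$peaks$n_pixels == 9))
  r13 <- find_hits(f, hit_params(min_peaks = 13))
  expect_equal(r13$n_peaks, 12)
  expect_false(r13$is_hit)
  # blank frame
  blank <- find_hits(matrix(0, 64, 64))
  expect_equal(blank$n_peaks, 0L)
  expect_false(blank$is_hit)
  # single-pixel peaks are rejected by min_pixels = 2
  g <- matrix(10, 64, 64)
  g[cbind(c(10, 30, 50), c(10, 30, 50))] <- 500
  expect_equal(find_hits(g, hit_params())$n_peaks, 0)
  expect_equal(find_hits(g, hit_params(min_pixels = 1))$n_peaks, 3)
})

test_that("the analysis pipeline recovers truth on a three-region scan", {
  lay <- test_layout()
  geom <- test_geometry(64)
  sm <- three_region_scene_map(lay)
  scan <- simulate_scan(lay, geom, sm, n_shots = 300, stride = 100,
                        seed = 42)
  expect_gt(length(unique(scan$shots$true_region)), 2)
  tab <- analyze_scan(scan, geom)
  # classification against simulator truth
  acc <- mean(as.character(tab$population) == tab$true_region)
  expect_gte(acc, 0.95)
  # median recovery in the moderate population
  mod <- tab$true_region == "moderate"
  if (any(mod)) {
    expect_lt(abs(stats::median(tab$median_pp[mod]) - 20), 1)
  }
  # hit flags against truth occupancy
  expect_gte(mean(tab$is_hit == tab$true_is_hit), 0.95)
  # pipeline determinism, byte for byte
  tab2 <- analyze_scan(scan, geom)
  attr(tab, "calibration") <- attr(tab2, "calibration") <- NULL
  expect_identical(tab, tab2)
})

test_that("saturation masking drops pixels from the median", {
  f <- matrix(30, 32, 32)          # 1 photon at gain 30
  f[1:16, ] <- 6e4                 # saturated half
  cal <- list(adu_per_photon = 30, zero_offset = 0)
  scanlike <- list(frames = list(structure(
    list(pixels = f, pulse_energy_mj = 1), class = "sfx_frame")))
  out <- analyze_scan(scanlike, test_geometry(32), calibration = cal,
                      saturation_adu = 5e4)
  expect_equal(out$median_pp, 1)
})
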