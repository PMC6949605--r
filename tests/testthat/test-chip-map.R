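# Chip-coordinate maps, hit-rate fields, row/time series, colocalization.

sim_tab <- function(lay, n = 200, stride = 50, seed = 5) {
  sm <- three_region_scene_map(lay)
  simulate_scan(lay, test_geometry(16), sm, n_shots = n, stride = stride,
                seed = seed, render = FALSE)$shots
}

test_that("a single shot maps to exactly one non-missing pore", {
  lay <- test_layout(1, 1)
  shots <- sim_tab(lay, n = 1, stride = 1)
  m <- map_shots(shots, lay, value_column = "true_median_pp")
  expect_equal(sum(!is.na(m$value)), 1)
  expect_equal(m$value[!is.na(m$value)], shots$true_median_pp)
  expect_equal(nrow(m), nrow(lay$pores))  # unvisited pores retained as NA
})

test_that("mapping is invariant under shot order and rejects off-chip shots", {
  lay <- test_layout(1, 2)
  shots <- sim_tab(lay, n = 150, stride = 10)
  m1 <- map_shots(shots, lay, "true_median_pp")
  m2 <- map_shots(shots[sample.int(nrow(shots)), ], lay, "true_median_pp")
  expect_identical(m1$value, m2$value)
  bad <- shots
  bad$pore_x_mm[3] <- 99.9
  expect_error(map_shots(bad, lay, "true_median_pp"), "off the chip")
})

test_that("per-region map means track the region truth medians", {
  lay <- test_layout()
  sm <- three_region_scene_map(lay)
  scan <- simulate_scan(lay, test_geometry(64), sm, n_shots = 250,
                        stride = 120, seed = 9)
  tab <- analyze_scan(scan, test_geometry(64))
  m <- map_shots(tab, lay, "median_pp")
  med_by_region <- tapply(tab$median_pp, tab$true_region, mean)
  targets <- c(low = 2, moderate = 20, high = 50)
  for (r in names(med_by_region)) {
    expect_lt(abs(med_by_region[[r]] / targets[[r]] - 1), 0.05)
  }
})

test_that("hit-rate field averages Bernoulli hits to the loading rate", {
  lay <- test_layout(2, 4)
  shots <- sim_tab(lay, n = 4000, stride = 2, seed = 17)
  set.seed(17)
  shots$is_hit <- stats::runif(nrow(shots)) < 0.3
  hf <- hit_rate_field(shots, lay, radius_um = 250)
  expect_true(all(hf$hit_rate >= 0 & hf$hit_rate <= 1, na.rm = TRUE))
  expect_lt(abs(mean(hf$hit_rate, na.rm = TRUE) - 0.30), 0.02)
  expect_true(all(hf$n_shots[!is.na(hf$hit_rate)] > 0))
  expect_error(hit_rate_field(shots, lay, radius_um = 0), "positive")
})

test_that("a vanishing radius degenerates to per-shot indicators", {
  lay <- test_layout(1, 1)
  shots <- sim_tab(lay, n = 50, stride = 3, seed = 23)
  shots$is_hit <- shots$true_is_hit
  hf <- hit_rate_field(shots, lay, radius_um = 1)  # << pore spacing
  expect_equal(hf$hit_rate, as.numeric(shots$is_hit))
  expect_true(all(hf$n_shots == 1))
})

test_that("two-region hit structure is recovered by thresholding the field", {
  lay <- test_layout(2, 4)
  shots <- sim_tab(lay, n = 3000, stride = 2, seed = 29)
  set.seed(29)
  left <- shots$pore_x_mm < 3.2
  p <- ifelse(left, 0.05, 0.5)
  shots$is_hit <- stats::runif(nrow(shots)) < p
  hf <- hit_rate_field(shots, lay, radius_um = 250)
  pred_left <- hf$hit_rate < 0.275
  truth_left <- hf$x_mm < 3.2
  ok <- !is.na(hf$hit_rate)
  expect_gte(mean(pred_left[ok] == truth_left[ok]), 0.90)
})

test_that("row/time ordering matches an independent sort oracle", {
  lay <- test_layout(1, 2)
  shots <- sim_tab(lay, n = 120, stride = 11, seed = 31)
  shuf <- shots[sample.int(nrow(shots)), ]
  rt <- row_time_series(shuf, value_column = "true_median_pp")
  oracle <- shots[order(shots$chip_row, shots$timestamp), ]
  rownames(oracle) <- NULL
  expect_identical(rt$series$shot_id, oracle$shot_id)
  # already-sorted input passes through unchanged
  rt2 <- row_time_series(rt$series, value_column = "true_median_pp")
  expect_identical(rt2$series, rt$series)
  # constant column summarises to the constant in every row
  shots$const <- 7.5
  rts <- row_time_series(shots, value_column = "const")
  expect_true(all(rts$by_row$mean == 7.5))
  dup <- shots
  dup$shot_id[2] <- dup$shot_id[1]
  expect_error(row_time_series(dup, value_column = "true_median_pp"),
               "duplicate")
})

test_that("colocalization ratio reflects the hit/background coupling", {
  lay <- test_layout(2, 4)
  shots <- sim_tab(lay, n = 4000, stride = 2, seed = 37)
  # null: hits independent of intensity -> ratio ~ 1
  set.seed(37)
  shots$is_hit <- stats::runif(nrow(shots)) < 0.2
  shots$median_pp <- shots$true_median_pp
  r0 <- colocalization_report(shots, stats::median(shots$median_pp))
  expect_lt(abs(r0$ratio - 1), 0.25)
  # extreme: hits only above threshold -> below-stratum rate 0, ratio Inf
  shots$is_hit <- shots$median_pp > stats::median(shots$median_pp)
  r1 <- colocalization_report(shots, stats::median(shots$median_pp))
  expect_identical(r1$rate_below, 0)
  expect_identical(r1$ratio, Inf)
  # empty stratum -> missing ratio
  r2 <- colocalization_report(shots, -1)
  expect_true(is.na(r2$ratio))
})

test_that("wet-pocket simulations colocalise hits with high background", {
  lay <- test_layout()
  shots <- sim_tab(lay, n = 6000, stride = 5, seed = 41)
  shots$is_hit <- shots$true_is_hit
  shots$median_pp <- shots$true_median_pp
  r <- colocalization_report(shots, threshold_pp = 7)
  # occupancy 0.28 vs 0.05 -> hit-rate ratio ~ 4.9
  expect_gt(r$ratio, 4)
  expect_lt(r$ratio, 6)
})
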