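# Chip-coordinate maps: arrange per-shot statistics spatially (heat maps of
# median background, smoothed hit-rate fields) and order them by scan row
# and time for drift inspection.

#' Map per-shot values onto chip pore positions
#'
#' Assigns each shot's value to its pore on the layout, preserving values
#' exactly. Pores never visited are kept in the map with `NA` (missing, not
#' zero). The result is independent of the order of the shot rows.
#'
#' @param shots analysed shot table with `pore_x_mm`, `pore_y_mm` and the
#'   value column.
#' @param layout an [make_chip_layout()] object.
#' @param value_column name of the column to map (e.g. `"median_pp"`).
#' @param tol_mm matching tolerance between shot and pore coordinates.
#' @return object of class `sfx_chip_map`: `data.frame` with `pore_id`,
#'   `x_mm`, `y_mm`, `value`, `visited`; attribute `value_column`.
#' @export
map_shots <- function(shots, layout, value_column = "median_pp",
                      tol_mm = 1e-6) {
  stopifnot(inherits(layout, "sfx_chip_layout"),
            value_column %in% names(shots))
  pores <- layout$pores
  key <- function(x, y) paste(round(x / tol_mm), round(y / tol_mm))
  idx <- match(key(shots$pore_x_mm, shots$pore_y_mm),
               key(pores$x_mm, pores$y_mm))
  if (anyNA(idx)) {
    bad <- which(is.na(idx))
    stop("shots at positions off the chip layout: shot rows ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ..." else "")
  }
  value <- rep(NA_real_, nrow(pores))
  value[idx] <- shots[[value_column]]
  out <- data.frame(pore_id = pores$pore_id, x_mm = pores$x_mm,
                    y_mm = pores$y_mm, value = value,
                    visited = !is.na(value) | seq_len(nrow(pores)) %in% idx)
  attr(out, "value_column") <- value_column
  class(out) <- c("sfx_chip_map", "data.frame")
  out
}

#' Spatially smoothed hit-rate field
#'
#' At each visited pore, the fraction of hits among all shots within a disk
#' of the given radius (unweighted top-hat average, or Gaussian-weighted).
#' Points with no contributing shots are missing, never zero-filled.
#'
#' @param shots analysed shot table with `pore_x_mm`, `pore_y_mm` and a
#'   logical `is_hit` column (truth column `true_is_hit` works too via
#'   `hit_column`).
#' @param layout an [make_chip_layout()] object.
#' @param radius_um smoothing radius in um; must exceed the pore spacing.
#' @param hit_column name of the logical hit column.
#' @param weighting `"tophat"` (unweighted disk) or `"gaussian"` (sigma =
#'   radius/2, truncated at 3 sigma).
#' @return `data.frame` of class `sfx_hit_field`: `x_mm`, `y_mm`,
#'   `hit_rate` in `[0, 1]`, `n_shots` contributing.
#' @export
hit_rate_field <- function(shots, layout, radius_um = 250,
                           hit_column = "is_hit",
                           weighting = c("tophat", "gaussian")) {
  weighting <- match.arg(weighting)
  if (radius_um <= 0) stop("radius must be positive")
  stopifnot(hit_column %in% names(shots))
  r_mm <- radius_um / 1000
  hx <- shots$pore_x_mm; hy <- shots$pore_y_mm
  hit <- as.logical(shots[[hit_column]])
  # evaluation points: the visited pores
  ex <- hx; ey <- hy
  # cell-list over a grid of side r to avoid the full distance matrix
  cell <- function(x, y) paste(floor(x / r_mm), floor(y / r_mm))
  shot_cell <- cell(hx, hy)
  cell_index <- split(seq_along(hx), shot_cell)
  rate <- numeric(length(ex)); nsh <- integer(length(ex))
  for (i in seq_along(ex)) {
    cx <- floor(ex[i] / r_mm); cy <- floor(ey[i] / r_mm)
    neigh <- as.vector(outer(cx + (-1:1), cy + (-1:1), paste))
    cand <- unlist(cell_index[neigh], use.names = FALSE)
    d2 <- (hx[cand] - ex[i])^2 + (hy[cand] - ey[i])^2
    sel <- cand[d2 <= r_mm^2]
    if (!length(sel)) { rate[i] <- NA_real_; nsh[i] <- 0L; next }
    if (weighting == "tophat") {
      rate[i] <- mean(hit[sel])
    } else {
      w <- exp(-d2[d2 <= r_mm^2] / (2 * (r_mm / 2)^2))
      rate[i] <- sum(w * hit[sel]) / sum(w)
    }
    nsh[i] <- length(sel)
  }
  out <- data.frame(x_mm = ex, y_mm = ey, hit_rate = rate, n_shots = nsh)
  attr(out, "radius_um") <- radius_um
  class(out) <- c("sfx_hit_field", "data.frame")
  out
}

#' Order shots by chip row and time
#'
#' Stable sort by (chip row, timestamp), the ordering used to inspect
#' background drift along the scan, plus per-row summaries.
#'
#' @param shots shot table with `chip_row`, `timestamp`, `shot_id`.
#' @param value_column column to summarise per row.
#' @return list with `series` (the sorted table) and `by_row`
#'   (`data.frame`: `chip_row`, `n`, `mean`, `median`).
#' @export
row_time_series <- function(shots, value_column = "median_pp") {
  stopifnot(all(c("chip_row", "timestamp", "shot_id") %in% names(shots)),
            value_column %in% names(shots))
  if (anyDuplicated(shots$shot_id)) {
    stop("duplicate shot_ids in shot table")
  }
  ord <- order(shots$chip_row, shots$timestamp)
  series <- shots[ord, , drop = FALSE]
  rownames(series) <- NULL
  v <- split(series[[value_column]], series$chip_row)
  by_row <- data.frame(chip_row = as.integer(names(v)),
                       n = lengths(v),
                       mean = vapply(v, mean, numeric(1)),
                       median = vapply(v, stats::median, numeric(1)))
  rownames(by_row) <- NULL
  list(series = series, by_row = by_row)
}

#' Do hits colocalise with high background?
#'
#' Splits shots at a median-intensity threshold and compares the hit rate
#' above versus below, quantifying whether crystal hits cluster in regions
#' of thick enclosed water (high background).
#'
#' @param shots analysed shot table with `median_pp` and `is_hit` (or the
#'   columns named by `value_column` / `hit_column`).
#' @param threshold_pp intensity threshold in photons/pixel (per mJ if the
#'   table is normalised).
#' @param value_column,hit_column column names.
#' @return list: `rate_above`, `rate_below`, `ratio` (above/below; `NA`
#'   when a stratum is empty or the below rate is 0 with `Inf` when hits
#'   exist above), `n_above`, `n_below`.
#' @export
colocalization_report <- function(shots, threshold_pp,
                                  value_column = "median_pp",
                                  hit_column = "is_hit") {
  stopifnot(value_column %in% names(shots), hit_column %in% names(shots))
  v <- shots[[value_column]]
  h <- as.logical(shots[[hit_column]])
  above <- v > threshold_pp
  n_above <- sum(above); n_below <- sum(!above)
  rate_above <- if (n_above) mean(h[above]) else NA_real_
  rate_below <- if (n_below) mean(h[!above]) else NA_real_
  ratio <- if (!n_above || !n_below) {
    NA_real_
  } else if (rate_below == 0) {
    if (rate_above > 0) Inf else NA_real_
  } else {
    rate_above / rate_below
  }
  list(rate_above = rate_above, rate_below = rate_below, ratio = ratio,
       n_above = n_above, n_below = n_below)
}

#' Write a chip map or hit-rate field as long-format TSV
#' @param x an `sfx_chip_map` or `sfx_hit_field`.
#' @param path output file.
#' @export
write_chip_map <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
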