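# Per-shot background analysis: pulse-energy-normalised radial profiles,
# robust median intensity, population classification against the fixed
# photon/pixel thresholds, and threshold-plus-SNR hit finding.

#' Radial (azimuthal) average of a frame
#'
#' Mean photon value in annular bins about the beam centre, expressed
#' against the scattering-vector magnitude q, optionally divided by the
#' pulse energy.
#'
#' @param frame photon-valued matrix matching the geometry, or `sfx_frame`
#'   (then `photons` must already be converted; pass a matrix for clarity).
#' @param geometry an [detector_geometry()] object.
#' @param n_bins number of equal-width q bins between 0 and the detector
#'   maximum.
#' @param pulse_energy_mj divide the profile by this pulse energy; `NULL`
#'   leaves the profile unnormalised.
#' @param mask optional logical matrix, `TRUE` for valid pixels.
#' @return object of class `sfx_radial_profile`: `data.frame` with
#'   `q_center` (1/Angstrom), `mean_intensity`, `n_pixels`; attribute
#'   `normalized` records whether per-mJ normalisation was applied.
#' @export
radial_average <- function(frame, geometry, n_bins = 100,
                           pulse_energy_mj = NULL, mask = NULL) {
  px <- if (inherits(frame, "sfx_frame")) frame$pixels else frame
  stopifnot(inherits(geometry, "sfx_geometry"))
  if (nrow(px) != geometry$n_fast || ncol(px) != geometry$n_slow) {
    stop("frame shape does not match detector geometry")
  }
  if (geometry$beam_center[1] < 1 || geometry$beam_center[1] > geometry$n_fast ||
      geometry$beam_center[2] < 1 || geometry$beam_center[2] > geometry$n_slow) {
    stop("beam centre lies outside the frame")
  }
  qm <- q_map(geometry)
  keep <- if (is.null(mask)) rep(TRUE, length(px)) else as.logical(mask)
  qv <- qm[keep]; pv <- px[keep]
  edges <- seq(0, max(qm), length.out = n_bins + 1)
  bin <- pmin(findInterval(qv, edges, rightmost.closed = TRUE), n_bins)
  sums <- tabulate(bin, n_bins)
  tot <- vapply(split(pv, factor(bin, levels = seq_len(n_bins))), sum,
                numeric(1))
  m <- ifelse(sums > 0, tot / sums, NA_real_)
  if (!is.null(pulse_energy_mj)) {
    stopifnot(pulse_energy_mj > 0)
    m <- m / pulse_energy_mj
  }
  structure(data.frame(q_center = (edges[-1] + edges[-(n_bins + 1)]) / 2,
                       mean_intensity = m, n_pixels = sums),
            normalized = !is.null(pulse_energy_mj),
            class = c("sfx_radial_profile", "data.frame"))
}

#' Per-shot median intensity
#'
#' Median photons per pixel over the valid pixels, divided by the pulse
#' energy. The median (rather than the mean) makes the statistic robust to
#' the sharp Bragg reflections a hit superimposes on the smooth background.
#'
#' @param frame photon-valued matrix (or `sfx_frame`, whose `pixels` are
#'   then used as-is).
#' @param pulse_energy_mj pulse energy; use 1 for an unnormalised median.
#' @param mask optional logical matrix of valid pixels.
#' @return median photons per pixel per mJ.
#' @export
median_intensity <- function(frame, pulse_energy_mj = 1, mask = NULL) {
  px <- if (inherits(frame, "sfx_frame")) frame$pixels else frame
  stopifnot(pulse_energy_mj > 0)
  if (!is.null(mask)) px <- px[as.logical(mask)]
  px <- px[!is.na(px)]
  if (!length(px)) stop("no valid pixels for median intensity")
  stats::median(px) / pulse_energy_mj
}

#' Classify a shot by its median background intensity
#'
#' Background populations on an enclosed chip separate into three groups:
#' very low (< 5 photons/pixel, dry or thin-film regions), moderate
#' (10-35, wet pockets of enclosed buffer), and very high (> 40, shots on
#' the polyimide support frame). Values in the gaps (5, 10) and (35, 40]
#' are reported as `unclassified`.
#'
#' @param median_pp median photons per pixel (vectorised, must be >= 0).
#' @param thresholds numeric of length 4: low max, moderate min, moderate
#'   max, high min.
#' @return factor with levels `low`, `moderate`, `high`, `unclassified`.
#' @export
classify_shot <- function(median_pp, thresholds = c(5, 10, 35, 40)) {
  if (any(median_pp < 0, na.rm = TRUE)) {
    stop("median intensity must be non-negative")
  }
  stopifnot(length(thresholds) == 4, !is.unsorted(thresholds))
  out <- rep("unclassified", length(median_pp))
  out[median_pp < thresholds[1]] <- "low"
  out[median_pp >= thresholds[2] & median_pp <= thresholds[3]] <- "moderate"
  out[median_pp > thresholds[4]] <- "high"
  factor(out, levels = c("low", "moderate", "high", "unclassified"))
}

#' Default hit-finding parameters
#'
#' Threshold-based peak finding with the standard serial-crystallography
#' settings: minimum peak intensity 200 ADU, minimum signal-to-noise 6,
#' minimum 2 pixels per peak and minimum 10 peaks per hit.
#'
#' @param min_adu intensity threshold in frame units.
#' @param min_snr peak max must exceed local background by this many local
#'   robust sigmas.
#' @param min_pixels minimum connected pixels per peak.
#' @param min_peaks minimum peaks for a frame to count as a hit.
#' @param tile_px tile size for the local median/MAD background estimate.
#' @return list of parameters.
#' @export
hit_params <- function(min_adu = 200, min_snr = 6, min_pixels = 2,
                       min_peaks = 10, tile_px = 32) {
  stopifnot(min_adu > 0, min_snr > 0, min_pixels >= 1, min_peaks >= 1,
            tile_px >= 4)
  list(min_adu = min_adu, min_snr = min_snr, min_pixels = min_pixels,
       min_peaks = min_peaks, tile_px = tile_px)
}

# Tile-wise local background (median) and robust sigma (MAD) expanded back
# to pixel resolution. Returns matrices the shape of `px`.
.local_background <- function(px, tile_px) {
  nf <- nrow(px); ns <- ncol(px)
  ti <- ceiling(seq_len(nf) / tile_px)
  tj <- ceiling(seq_len(ns) / tile_px)
  nti <- max(ti)
  tid <- matrix(ti, nf, ns) + (matrix(tj, nf, ns, byrow = TRUE) - 1L) * nti
  sp <- split(as.numeric(px), as.integer(tid))
  medv <- vapply(sp, stats::median, numeric(1))
  madv <- vapply(sp, stats::mad, numeric(1))
  keys <- as.integer(names(sp))
  med_lut <- sig_lut <- numeric(max(keys))
  med_lut[keys] <- medv
  sig_lut[keys] <- pmax(madv, 1e-6)
  list(median = matrix(med_lut[tid], nf, ns),
       sigma = matrix(sig_lut[tid], nf, ns))
}

# Azimuthal (annulus) median and MAD background, ~4 px wide rings about the
# beam centre. Bragg spots occupy a negligible fraction of an annulus, so
# the median tracks the smooth scattering profile through the water ring.
.radial_bin_cache <- new.env(parent = emptyenv())
.radial_background <- function(px, geometry, ring_px = 4) {
  nf <- nrow(px); ns <- ncol(px)
  key <- paste(nf, ns, geometry$beam_center[1], geometry$beam_center[2],
               ring_px, sep = "_")
  bin <- .radial_bin_cache[[key]]
  if (is.null(bin)) {
    fx <- seq_len(nf) - geometry$beam_center[1]
    sy <- seq_len(ns) - geometry$beam_center[2]
    r <- sqrt(outer(fx^2, sy^2, `+`))
    bin <- matrix(as.integer(r / ring_px) + 1L, nf, ns)
    .radial_bin_cache[[key]] <- bin
  }
  sp <- split(as.numeric(px), as.integer(bin))
  medv <- vapply(sp, stats::median, numeric(1))
  madv <- vapply(sp, stats::mad, numeric(1))
  keys <- as.integer(names(sp))
  med_lut <- sig_lut <- numeric(max(keys))
  med_lut[keys] <- medv
  sig_lut[keys] <- pmax(madv, 1e-6)
  list(median = matrix(med_lut[bin], nf, ns),
       sigma = matrix(sig_lut[bin], nf, ns))
}

#' Find Bragg peaks and flag hits
#'
#' Candidate pixels exceed the local background by at least `min_adu` frame
#' units; their connected components count as peaks when the component
#' maximum also exceeds the background by `min_snr` local robust sigmas and
#' the component holds at least `min_pixels` pixels. A frame with at least
#' `min_peaks` peaks is a hit. Thresholding above the local background
#' (rather than in absolute units) keeps the intensity threshold meaningful
#' on frames whose smooth water background alone exceeds it. When a
#' detector geometry is supplied the background and sigma are azimuthal
#' annulus medians/MADs (which follow the steep water-ring gradient); the
#' fallback is a square-tile median/MAD.
#'
#' @param frame numeric matrix (ADU or photons; thresholds are in frame
#'   units) or `sfx_frame`.
#' @param params see [hit_params()].
#' @param geometry optional [detector_geometry()]; enables the radial
#'   background model.
#' @return list with `peaks` (`data.frame`: `x`, `y`, `n_pixels`,
#'   `max_value`, `snr`), `n_peaks` and `is_hit`.
#' @export
find_hits <- function(frame, params = hit_params(), geometry = NULL) {
  px <- if (inherits(frame, "sfx_frame")) frame$pixels else frame
  bg <- if (is.null(geometry)) {
    .local_background(px, params$tile_px)
  } else {
    .radial_background(px, geometry)
  }
  excess <- px - bg$median
  above <- excess >= params$min_adu
  empty <- list(peaks = data.frame(x = integer(), y = integer(),
                                   n_pixels = integer(),
                                   max_value = numeric(), snr = numeric()),
                n_peaks = 0L, is_hit = FALSE)
  if (!any(above)) return(empty)
  labv <- as.integer(EBImage::bwlabel(matrix(as.numeric(above), nrow(px))))
  idx <- which(labv > 0L)
  comp <- labv[idx]
  sizes <- tabulate(comp)
  # per-component argmax, vectorised: order by (component, value) and take
  # the last index of each group
  ord <- order(comp, px[idx])
  idx <- idx[ord]; comp <- comp[ord]
  last <- cumsum(sizes)
  imax <- idx[last]
  snr <- (px[imax] - bg$median[imax]) / bg$sigma[imax]
  peaks <- data.frame(x = ((imax - 1) %% nrow(px)) + 1,
                      y = ((imax - 1) %/% nrow(px)) + 1,
                      n_pixels = sizes, max_value = px[imax], snr = snr)
  peaks <- peaks[peaks$n_pixels >= params$min_pixels &
                 peaks$snr >= params$min_snr, , drop = FALSE]
  rownames(peaks) <- NULL
  list(peaks = peaks, n_peaks = nrow(peaks),
       is_hit = nrow(peaks) >= params$min_peaks)
}

#' Run the per-shot analysis pipeline over a scan
#'
#' Applies gain conversion, saturation masking, median intensity,
#' population classification and hit finding to every frame of a simulated
#' (or loaded) scan, producing the analysis shot table. Deterministic:
#' identical frames and configuration give identical tables.
#'
#' @param scan result of [simulate_scan()] (with frames), or a list of
#'   `sfx_frame` objects.
#' @param geometry an [detector_geometry()] object.
#' @param calibration gain calibration from [estimate_gain()], or `"auto"`
#'   to estimate it from the scan's own frames. Auto-calibration pools the
#'   quarter of frames with the lowest median ADU, where the zero- and
#'   single-photon peaks are best populated.
#' @param params hit-finding parameters, see [hit_params()].
#' @param saturation_adu pixels at or above this ADU level are masked before
#'   the median (detector saturation guard); `Inf` disables.
#' @param normalize divide medians by the shot pulse energy (photons per
#'   pixel per mJ) or leave them raw.
#' @return `data.frame` (the analysed shot table): per shot the scan
#'   metadata, `median_pp`, `population`, `n_peaks`, `is_hit`, plus any
#'   truth columns carried through.
#' @export
analyze_scan <- function(scan, geometry, calibration = "auto",
                         params = hit_params(), saturation_adu = Inf,
                         normalize = TRUE) {
  frames <- if (!is.null(scan$frames)) scan$frames else scan
  stopifnot(length(frames) >= 1)
  if (identical(calibration, "auto")) {
    meds <- vapply(frames, function(f) {
      stats::median(if (inherits(f, "sfx_frame")) f$pixels else f)
    }, numeric(1))
    low <- which(meds <= stats::quantile(meds, 0.25))
    calibration <- estimate_gain(frames[low])
  }
  meta <- if (!is.null(scan$shots)) scan$shots else
    data.frame(shot_id = seq_along(frames))
  n <- length(frames)
  med <- numeric(n); npk <- integer(n); hit <- logical(n)
  for (i in seq_len(n)) {
    fr <- frames[[i]]
    px <- if (inherits(fr, "sfx_frame")) fr$pixels else fr
    pe <- if (inherits(fr, "sfx_frame")) fr$pulse_energy_mj else 1
    mask <- px < saturation_adu
    ph <- adu_to_photons(px, calibration)
    med[i] <- median_intensity(ph, if (normalize) pe else 1, mask = mask)
    res <- find_hits(px, params, geometry = geometry)
    npk[i] <- res$n_peaks
    hit[i] <- res$is_hit
  }
  out <- meta[seq_len(n), , drop = FALSE]
  out$median_pp <- med
  out$population <- classify_shot(med)
  out$n_peaks <- npk
  out$is_hit <- hit
  attr(out, "calibration") <- calibration
  out
}
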