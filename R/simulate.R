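# Synthetic 120 Hz chip-scan data with the statistical structure the
# analysis pipeline assumes: an isotropic per-shot background (broad liquid
# water ring plus a smooth enclosure term), Poisson pore occupancy driving
# sparse Bragg-spot hits, integer photon (Poisson) counting statistics,
# ADU gain with Gaussian read noise, and pulse-energy jitter.

#' Describe a per-shot background scene
#'
#' The expected photon field is an isotropic function of the scattering
#' vector: a Gaussian water ring plus a flat term, scaled either so that the
#' median expected photons/pixel equals `median_pp` at the nominal pulse
#' energy, or so that the detector-summed expectation equals
#' `total_photons`. Bragg spots are added when the probed pore is occupied.
#'
#' @param median_pp target median expected photons per pixel at nominal
#'   pulse energy (ignored when `total_photons` is given).
#' @param total_photons alternative normalisation: detector-summed expected
#'   photons per shot at nominal pulse energy.
#' @param ring_q_center water-ring centre in 1/Angstrom.
#' @param ring_q_sigma Gaussian ring width in 1/Angstrom.
#' @param ring_weight,flat_weight relative amplitudes of the ring and the
#'   smooth (enclosure/gas) term; both must be non-negative.
#' @param occupancy_lambda mean crystals per probed pore for this region.
#' @param spots_per_crystal mean Bragg spots contributed per crystal.
#' @param spot_meanlog,spot_sdlog log-normal peak intensity (photons) of a
#'   Bragg spot. The default (median 150 photons) keeps spots several local
#'   sigmas above even the strongest background population, as Bragg
#'   reflections are in practice (detector saturation, not visibility, is
#'   the operational concern).
#' @param label region/population label stored in the shot truth.
#' @return object of class `sfx_scene`.
#' @export
scene <- function(median_pp = 20, total_photons = NULL,
                  ring_q_center = 2.0, ring_q_sigma = 0.5,
                  ring_weight = 1, flat_weight = 0.15,
                  occupancy_lambda = 0,
                  spots_per_crystal = 30,
                  spot_meanlog = log(150), spot_sdlog = 0.7,
                  label = "scene") {
  if (ring_weight < 0 || flat_weight < 0 || (ring_weight + flat_weight) <= 0) {
    stop("scene amplitudes must be non-negative and not all zero")
  }
  if (ring_q_center < 0 || ring_q_sigma <= 0) {
    stop("invalid water-ring q parameters")
  }
  stopifnot(median_pp >= 0, occupancy_lambda >= 0, spots_per_crystal >= 0)
  structure(list(median_pp = median_pp, total_photons = total_photons,
                 ring_q_center = ring_q_center, ring_q_sigma = ring_q_sigma,
                 ring_weight = ring_weight, flat_weight = flat_weight,
                 occupancy_lambda = occupancy_lambda,
                 spots_per_crystal = spots_per_crystal,
                 spot_meanlog = spot_meanlog, spot_sdlog = spot_sdlog,
                 label = label),
            class = "sfx_scene")
}

#' Detector gain model
#'
#' @param gain ADU per photon.
#' @param read_noise Gaussian read noise sigma in ADU.
#' @param offset zero-photon baseline in ADU.
#' @return object of class `sfx_gain_model`.
#' @export
gain_model <- function(gain = 30, read_noise = 3, offset = 0) {
  stopifnot(gain > 0, read_noise >= 0)
  structure(list(gain = gain, read_noise = read_noise, offset = offset),
            class = "sfx_gain_model")
}

# Expected-photon field of a scene on a detector, at nominal pulse energy.
# Cached per (scene, geometry) by the caller.
.scene_field <- function(sc, geometry, qm = q_map(geometry)) {
  if (sc$ring_q_center > max(qm) + 3 * sc$ring_q_sigma) {
    stop("water-ring q centre lies far outside the detector q range")
  }
  shape <- sc$ring_weight *
    exp(-(qm - sc$ring_q_center)^2 / (2 * sc$ring_q_sigma^2)) +
    sc$flat_weight
  if (!is.null(sc$total_photons)) {
    scale <- sc$total_photons / sum(shape)
  } else if (sc$median_pp == 0) {
    scale <- 0
  } else {
    scale <- sc$median_pp / stats::median(shape)
  }
  shape * scale
}

# Add k Bragg-spot disks (radius 1-2 px) at uniform positions to an
# expected-photon field. Returns the field.
.add_spots <- function(field, k, sc) {
  if (k <= 0) return(field)
  nf <- nrow(field); ns <- ncol(field)
  cx <- sample.int(nf, k, replace = TRUE)
  cy <- sample.int(ns, k, replace = TRUE)
  rad <- sample(1:2, k, replace = TRUE)
  amp <- stats::rlnorm(k, sc$spot_meanlog, sc$spot_sdlog)
  for (i in seq_len(k)) {
    xs <- max(1, cx[i] - rad[i]):min(nf, cx[i] + rad[i])
    ys <- max(1, cy[i] - rad[i]):min(ns, cy[i] + rad[i])
    d2 <- outer((xs - cx[i])^2, (ys - cy[i])^2, `+`)
    disk <- d2 <= rad[i]^2
    field[xs, ys][disk] <- field[xs, ys][disk] + amp[i]
  }
  field
}

#' Simulate one detector frame
#'
#' Draws the pixel ADU array for a single shot: Poisson photons from the
#' scene's expected field (times the pulse-energy ratio), Bragg spots when
#' `n_crystals > 0`, then `ADU = gain * photons + N(offset, read_noise)`.
#' Uses the current RNG state unless `seed` is given.
#'
#' @param geometry an [detector_geometry()] object.
#' @param sc an [scene()] object.
#' @param gm an [gain_model()] object.
#' @param pulse_energy_mj pulse energy of this shot; the expected field
#'   scales linearly with it relative to `nominal_pulse_mj`.
#' @param nominal_pulse_mj pulse energy at which the scene is normalised.
#' @param n_crystals pore occupancy; `NULL` draws it from
#'   `Poisson(occupancy_lambda)`.
#' @param seed optional integer seed for a reproducible single frame.
#' @param field optional precomputed expected field (from an internal cache)
#'   to avoid recomputing the q map per shot.
#' @return object of class `sfx_frame`: list with `pixels` (ADU matrix),
#'   `pulse_energy_mj` and a `truth` list (`n_crystals`, `n_spots`,
#'   `true_median_pp`, `label`).
#' @export
simulate_shot <- function(geometry, sc, gm = gain_model(),
                          pulse_energy_mj = 1, nominal_pulse_mj = 1,
                          n_crystals = NULL, seed = NULL, field = NULL) {
  stopifnot(inherits(geometry, "sfx_geometry"), inherits(sc, "sfx_scene"),
            pulse_energy_mj > 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(field)) field <- .scene_field(sc, geometry)
  lam <- field * (pulse_energy_mj / nominal_pulse_mj)
  if (is.null(n_crystals)) n_crystals <- stats::rpois(1, sc$occupancy_lambda)
  n_spots <- 0L
  if (n_crystals > 0) {
    n_spots <- stats::rpois(1, sc$spots_per_crystal * n_crystals)
    lam <- .add_spots(lam, n_spots, sc)
  }
  npix <- length(lam)
  photons <- matrix(stats::rpois(npix, lam), nrow(lam), ncol(lam))
  adu <- gm$gain * photons + gm$offset
  if (gm$read_noise > 0) adu <- adu + stats::rnorm(npix, 0, gm$read_noise)
  structure(list(pixels = adu, pulse_energy_mj = pulse_energy_mj,
                 truth = list(n_crystals = n_crystals, n_spots = n_spots,
                              true_median_pp = stats::median(lam),
                              label = sc$label)),
            class = "sfx_frame")
}

#' Region-to-scene map reproducing the three background populations
#'
#' Assigns a scene to each chip position: a high-intensity band where the
#' polyimide (Kapton) support frame overlaps the scan area, moderate
#' "wet pocket" regions where the enclosed water layer is thick, and a low
#' background elsewhere. Defaults give median backgrounds of 50 / 20 / 2
#' photons/pixel and make hits several times likelier in wet regions.
#'
#' @param layout an [make_chip_layout()] object.
#' @param frame_band_mm width of the frame band along the chip edge.
#' @param n_pockets,pocket_radius_mm wet-pocket count and radius.
#' @param lambda_low,lambda_wet pore occupancy in dry and wet/frame regions.
#' @param medians named vector of median photons/pixel for the three
#'   populations.
#' @param seed seed fixing the pocket positions.
#' @return list with `scenes` (named list) and `assign(x_mm, y_mm)`
#'   returning a scene name per position; class `sfx_scene_map`.
#' @export
three_region_scene_map <- function(layout, frame_band_mm = 1.0,
                                   n_pockets = 4, pocket_radius_mm = 1.2,
                                   lambda_low = 0.05, lambda_wet = 0.28,
                                   medians = c(low = 2, moderate = 20,
                                               high = 50),
                                   seed = 1L) {
  stopifnot(inherits(layout, "sfx_chip_layout"))
  chip <- layout$chip_mm
  # keep the frame band meaningful on small (test-sized) chips
  frame_band_mm <- min(frame_band_mm, 0.25 * min(chip))
  rng <- local({
    set.seed(seed)
    data.frame(x = stats::runif(n_pockets, frame_band_mm,
                                chip[1] - frame_band_mm),
               y = stats::runif(n_pockets, frame_band_mm,
                                chip[2] - frame_band_mm))
  })
  scenes <- list(
    low = scene(median_pp = medians[["low"]], occupancy_lambda = lambda_low,
                label = "low"),
    moderate = scene(median_pp = medians[["moderate"]],
                     occupancy_lambda = lambda_wet, label = "moderate"),
    high = scene(median_pp = medians[["high"]], occupancy_lambda = lambda_wet,
                 label = "high"))
  assign_fun <- function(x_mm, y_mm) {
    out <- rep("low", length(x_mm))
    for (i in seq_len(nrow(rng))) {
      d2 <- (x_mm - rng$x[i])^2 + (y_mm - rng$y[i])^2
      out[d2 <= pocket_radius_mm^2] <- "moderate"
    }
    edge <- x_mm < frame_band_mm | x_mm > chip[1] - frame_band_mm |
            y_mm < frame_band_mm | y_mm > chip[2] - frame_band_mm
    out[edge] <- "high"
    out
  }
  structure(list(scenes = scenes, assign = assign_fun, pockets = rng),
            class = "sfx_scene_map")
}

#' Wrap a single scene as a scene map
#' @param sc an [scene()] object applied everywhere.
#' @return an `sfx_scene_map`.
#' @export
uniform_scene_map <- function(sc) {
  structure(list(scenes = list(uniform = sc),
                 assign = function(x_mm, y_mm) rep("uniform", length(x_mm))),
            class = "sfx_scene_map")
}

#' Simulate a row-by-row chip scan
#'
#' Visits `n_shots` pores of the layout in row-major scan order at the
#' 120 Hz pulse rate, draws per-shot pulse energies with Gaussian jitter
#' (truncated at 10% of nominal), assigns each pore a scene from the scene
#' map, and renders frames. All randomness flows through `seed`: the same
#' seed and configuration give bit-identical output.
#'
#' @param layout an [make_chip_layout()] object.
#' @param geometry an [detector_geometry()] object.
#' @param scene_map an `sfx_scene_map` (see [three_region_scene_map()],
#'   [uniform_scene_map()]).
#' @param n_shots number of shots; together with `stride` must not exceed
#'   the pore count.
#' @param stride visit every `stride`-th pore in scan order (1 = contiguous
#'   scan). A sparse stride samples the whole chip area with few shots.
#' @param seed integer seed.
#' @param gm an [gain_model()].
#' @param nominal_pulse_mj nominal pulse energy in mJ.
#' @param jitter_cv coefficient of variation of the pulse energy.
#' @param scan_rate_hz shot repetition rate.
#' @param render if `FALSE`, skip frame rendering and return only the shot
#'   table with truth columns (fast path for occupancy statistics).
#' @return list with `frames` (list of `sfx_frame`, or `NULL`) and `shots`,
#'   a `data.frame` with one row per frame: `shot_id`, `timestamp`,
#'   `chip_row`, `chip_col`, `pore_x_mm`, `pore_y_mm`, `pulse_energy_mj`,
#'   and truth columns `true_n_crystals`, `true_is_hit`, `true_region`,
#'   `true_median_pp`.
#' @export
simulate_scan <- function(layout, geometry, scene_map, n_shots, seed = 1L,
                          stride = 1L, gm = gain_model(),
                          nominal_pulse_mj = 1, jitter_cv = 0.05,
                          scan_rate_hz = 120, render = TRUE) {
  stopifnot(inherits(layout, "sfx_chip_layout"),
            inherits(scene_map, "sfx_scene_map"), n_shots >= 1, stride >= 1)
  if ((n_shots - 1) * stride + 1 > nrow(layout$pores)) {
    stop("n_shots (", n_shots, ") at stride ", stride,
         " exceeds pore count (", nrow(layout$pores), ")")
  }
  set.seed(seed)
  pores <- layout$pores[seq(1L, by = stride, length.out = n_shots), ,
                        drop = FALSE]
  region <- scene_map$assign(pores$x_mm, pores$y_mm)
  bad <- setdiff(unique(region), names(scene_map$scenes))
  if (length(bad)) stop("scene map assigned unknown scene: ", bad[1])
  pulse <- nominal_pulse_mj * pmax(0.1, 1 + stats::rnorm(n_shots, 0, jitter_cv))
  lam_region <- vapply(scene_map$scenes, `[[`, numeric(1), "occupancy_lambda")
  n_cryst <- stats::rpois(n_shots, lam_region[region])

  fields <- NULL
  frames <- NULL
  true_med <- numeric(n_shots)
  if (render) {
    qm <- q_map(geometry)
    fields <- lapply(scene_map$scenes, .scene_field, geometry = geometry,
                     qm = qm)
    frames <- vector("list", n_shots)
    for (i in seq_len(n_shots)) {
      sc <- scene_map$scenes[[region[i]]]
      fr <- simulate_shot(geometry, sc, gm, pulse_energy_mj = pulse[i],
                          nominal_pulse_mj = nominal_pulse_mj,
                          n_crystals = n_cryst[i],
                          field = fields[[region[i]]])
      fr$shot_id <- i
      fr$timestamp <- (i - 1) / scan_rate_hz
      fr$chip_row <- pores$row[i]
      fr$chip_col <- pores$col[i]
      fr$pore_xy <- c(pores$x_mm[i], pores$y_mm[i])
      frames[[i]] <- fr
      true_med[i] <- fr$truth$true_median_pp
    }
  } else {
    med_region <- vapply(scene_map$scenes, `[[`, numeric(1), "median_pp")
    true_med <- med_region[region] * pulse / nominal_pulse_mj
  }
  shots <- data.frame(
    shot_id = seq_len(n_shots),
    timestamp = (seq_len(n_shots) - 1) / scan_rate_hz,
    chip_row = pores$row, chip_col = pores$col,
    pore_x_mm = pores$x_mm, pore_y_mm = pores$y_mm,
    pulse_energy_mj = pulse,
    true_n_crystals = n_cryst,
    true_is_hit = n_cryst >= 1L,
    true_region = region,
    true_median_pp = true_med,
    stringsAsFactors = FALSE)
  list(frames = frames, shots = shots)
}

#' Write a shot table as TSV
#' @param shots shot table `data.frame`.
#' @param path output file.
#' @export
write_shot_table <- function(shots, path) {
  utils::write.table(shots, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a shot table TSV
#' @param path file written by [write_shot_table()].
#' @export
read_shot_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
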