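# Single-photon gain calibration. At low occupancy the pooled single-pixel
# ADU histogram shows discrete peaks at 0, 1, 2, ... photons; the separation
# between the zero peak and the single-photon peak is the gain in ADU per
# photon. We locate the two modes on a smoothed histogram and refine with a
# shared-spacing Gaussian mixture fit.

#' Estimate detector gain from the single-photon peak
#'
#' Pools pixel values from a set of frames, histograms them, smooths the
#' histogram, locates the zero-photon and single-photon modes, and refines
#' the peak positions with a three-component Gaussian mixture whose photon
#' peaks share a common spacing (the gain).
#'
#' @param frames a list of `sfx_frame` objects, a list of matrices, or a
#'   single numeric vector/matrix of pixel ADU values.
#' @param max_pixels cap on the number of pooled pixel values (sampled
#'   deterministically by thinning, not randomly).
#' @param min_separation_sigma the single-photon peak must lie at least this
#'   many zero-peak sigmas above the zero peak to count as resolved.
#' @return object of class `sfx_gain_calibration`: `adu_per_photon`,
#'   `zero_offset`, `peak_positions`, `read_noise_adu`, `fit_quality`
#'   (relative RMS residual of the mixture fit).
#' @seealso [adu_to_photons()]
#' @export
estimate_gain <- function(frames, max_pixels = 4e6,
                          min_separation_sigma = 3) {
  v <- .pool_pixels(frames, max_pixels)
  if (length(v) < 1000) stop("too few pixels for gain calibration")

  # fine histogram (resolution well below any plausible gain); the top
  # 0.1% tail (Bragg spots) is excluded so it cannot dominate the binning
  vh <- v[v <= stats::quantile(v, 0.999)]
  h <- max(0.05, diff(range(vh)) / 6000)
  brk <- seq(min(vh) - h, max(vh) + 2 * h, by = h)
  hst <- graphics::hist(vh, breaks = brk, plot = FALSE)
  mids <- hst$mids
  cnt <- .smooth_counts(hst$counts)

  # peak spacing from the periodicity of the histogram: autocorrelation of
  # the baseline-subtracted counts peaks at the photon-peak period
  g0 <- .histogram_period(cnt) * h

  # prominent local maxima; the leftmost is the zero-photon peak (it need
  # not be the global mode when the mean occupancy is around 1 photon)
  cand <- .local_maxima(cnt)
  cand <- cand[cnt[cand] > 0.05 * max(cnt)]
  if (length(cand) >= 2 && is.na(g0)) {
    # weak periodicity (e.g. only two populated peaks): use the maxima
    acc <- .cluster_maxima(cand, cnt, mids, gate = diff(range(v)) / 50)
    if (length(acc) >= 2) g0 <- mids[acc[2]] - mids[acc[1]]
  }
  if (is.na(g0) || g0 <= 0) {
    stop("gain calibration failed: no periodic photon-peak structure in ",
         "the pixel histogram (peaks unresolved at this read noise?)")
  }
  # resolution gate: the main mode's half-width must be small against the
  # peak spacing, otherwise the photon peaks are merged and any apparent
  # period is noise
  m_idx <- which.max(cnt)
  half <- cnt[m_idx] / 2
  l_idx <- which(cnt[seq_len(m_idx)] < half)
  r_idx <- which(cnt[m_idx:length(cnt)] < half)
  if (length(l_idx) && length(r_idx)) {
    hwhm <- (mids[m_idx + r_idx[1] - 1] - mids[max(l_idx)]) / 2
    if (g0 < min_separation_sigma * hwhm / 1.177) {
      stop("gain calibration failed: zero- and single-photon peaks merge ",
           "(peak spacing ", signif(g0, 3), " ADU vs mode width ",
           signif(hwhm / 1.177, 3), " ADU)")
    }
  }
  cand <- .cluster_maxima(cand, cnt, mids, gate = 0.5 * g0)
  if (length(cand) < 2) {
    stop("gain calibration failed: fewer than two resolved photon peaks")
  }
  z0 <- mids[cand[1]]
  # zero-peak width from the curvature region around z0
  near <- abs(mids - z0) <= 0.4 * g0
  w <- cnt[near]
  sd0 <- sqrt(sum(w * (mids[near] - z0)^2) / sum(w))
  if (g0 < min_separation_sigma * sd0) {
    stop("gain calibration failed: zero- and single-photon peaks merge (",
         "separation ", signif(g0, 3), " ADU vs sigma ",
         signif(sd0, 3), " ADU)")
  }
  # peak-to-valley contrast: genuine photon peaks dip between modes;
  # ripples on a merged distribution do not
  h01 <- stats::approx(mids, cnt, xout = c(z0, z0 + g0))$y
  between <- mids > z0 + 0.2 * g0 & mids < z0 + 0.8 * g0
  if (any(between) && all(is.finite(h01))) {
    valley <- min(cnt[between])
    if (valley > 0.9 * min(h01)) {
      stop("gain calibration failed: no contrast between the zero- and ",
           "single-photon peaks (read noise too large for this gain?)")
    }
  }

  fit <- .fit_photon_peaks(mids, hst$counts, z0, g0, sd0)
  # fall back to the smoothed-histogram peaks if the fit ran away
  if (!is.finite(fit$gain) || fit$gain < 0.5 * g0 || fit$gain > 2 * g0) {
    fit <- list(gain = g0, z0 = z0, sigma0 = sd0, rel_rms = NA_real_)
  }
  structure(list(adu_per_photon = fit$gain,
                 zero_offset = fit$z0,
                 peak_positions = fit$z0 + fit$gain * (0:2),
                 read_noise_adu = fit$sigma0,
                 fit_quality = fit$rel_rms,
                 n_pixels = length(v)),
            class = "sfx_gain_calibration")
}

#' @export
print.sfx_gain_calibration <- function(x, ...) {
  cat(sprintf("<gain calibration> %.4g ADU/photon (zero offset %.3g ADU, read noise %.3g ADU)\n",
              x$adu_per_photon, x$zero_offset, x$read_noise_adu))
  cat(sprintf("  mixture fit relative RMS %.3g over %d pixels\n",
              x$fit_quality, x$n_pixels))
  invisible(x)
}

.pool_pixels <- function(frames, max_pixels) {
  if (inherits(frames, "sfx_frame")) frames <- list(frames)
  if (is.list(frames)) {
    v <- unlist(lapply(frames, function(f) {
      if (inherits(f, "sfx_frame")) as.numeric(f$pixels) else as.numeric(f)
    }), use.names = FALSE)
  } else {
    v <- as.numeric(frames)
  }
  if (length(v) > max_pixels) {
    v <- v[seq(1, length(v), length.out = max_pixels)]
  }
  v
}

.mode_of <- function(v) {
  d <- stats::density(v, n = 1024)
  d$x[which.max(d$y)]
}

.smooth_counts <- function(counts, k = 5) {
  kern <- stats::dnorm(seq(-2, 2, length.out = 2 * k + 1))
  kern <- kern / sum(kern)
  s <- as.numeric(stats::filter(counts, kern, sides = 2))
  s[is.na(s)] <- counts[is.na(s)]
  s
}

.local_maxima <- function(y) {
  n <- length(y)
  which(y > c(-Inf, y[-n]) & y >= c(y[-1], -Inf))
}

# Greedy clustering of local maxima: accept in decreasing height order,
# rejecting candidates within `gate` of an accepted one; returns bin
# indices sorted by position.
.cluster_maxima <- function(cand, cnt, mids, gate) {
  acc <- integer(0)
  for (i in cand[order(cnt[cand], decreasing = TRUE)]) {
    if (!length(acc) || all(abs(mids[i] - mids[acc]) >= gate)) {
      acc <- c(acc, i)
    }
  }
  sort(acc)
}

# Dominant period (in bins) of the photon-peak comb, from the
# autocorrelation of baseline-subtracted histogram counts. NA when no
# convincing periodicity exists.
.histogram_period <- function(cnt) {
  nb <- length(cnt)
  base <- stats::filter(cnt, rep(1 / (2 * (nb %/% 20) + 1),
                                 2 * (nb %/% 20) + 1), sides = 2)
  res <- cnt - as.numeric(base)
  res[is.na(res)] <- 0
  acv <- stats::acf(res, lag.max = nb %/% 2, plot = FALSE,
                    demean = TRUE)$acf[, 1, 1][-1]  # acv[k] = lag k
  n <- length(acv)
  # search beyond the zero-lag lobe: first local minimum
  mins <- which(acv < c(acv[-1], Inf) & acv <= c(Inf, acv[-n]))
  if (!length(mins) || mins[1] >= n - 2) return(NA_real_)
  lo <- mins[1]
  pk <- lo + which.max(acv[(lo + 1):n])
  if (acv[pk] < 0.05) return(NA_real_)  # no periodic structure
  lag <- pk
  # refine by local quadratic interpolation
  if (lag >= 2 && lag <= n - 1) {
    y1 <- acv[lag - 1]; y2 <- acv[lag]; y3 <- acv[lag + 1]
    d <- (y1 - y3) / (2 * (y1 - 2 * y2 + y3))
    if (is.finite(d) && abs(d) < 1) lag <- lag + d
  }
  lag
}

# Shared-spacing Gaussian mixture on the binned histogram: peaks at
# z0, z0+g, z0+2g with free amplitudes, one sigma for the zero peak and one
# for the photon peaks. Least squares via optim.
.fit_photon_peaks <- function(mids, counts, z0, g0, sd0) {
  win <- mids >= z0 - 4 * sd0 & mids <= z0 + 2.5 * g0
  x <- mids[win]; y <- counts[win]
  a0 <- max(counts) ; a1 <- max(counts[win & mids > z0 + g0 / 2], 1)
  par0 <- c(z0 = z0, g = g0, la0 = log(a0), la1 = log(a1),
            la2 = log(max(a1 / 10, 1)), ls0 = log(sd0), ls1 = log(sd0 * 1.2))
  model <- function(p) {
    exp(p["la0"]) * exp(-(x - p["z0"])^2 / (2 * exp(2 * p["ls0"]))) +
    exp(p["la1"]) * exp(-(x - p["z0"] - p["g"])^2 / (2 * exp(2 * p["ls1"]))) +
    exp(p["la2"]) * exp(-(x - p["z0"] - 2 * p["g"])^2 / (2 * exp(2 * p["ls1"])))
  }
  obj <- function(p) sum((model(p) - y)^2)
  fit <- stats::optim(par0, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  res <- sqrt(fit$value / length(y)) / max(y)
  list(gain = unname(fit$par["g"]), z0 = unname(fit$par["z0"]),
       sigma0 = unname(exp(fit$par["ls0"])), rel_rms = res)
}

#' Convert an ADU frame to photons
#'
#' `(ADU - zero_offset) / adu_per_photon`, clipped below at `floor`.
#'
#' @param frame numeric matrix of ADU, or an `sfx_frame`.
#' @param calibration an [estimate_gain()] result, or a list with
#'   `adu_per_photon` and `zero_offset`.
#' @param floor lower clip for the photon values (default 0; use `-Inf` to
#'   keep the noise-symmetric values).
#' @return numeric matrix of photons per pixel.
#' @export
adu_to_photons <- function(frame, calibration, floor = 0) {
  px <- if (inherits(frame, "sfx_frame")) frame$pixels else frame
  stopifnot(calibration$adu_per_photon > 0)
  ph <- (px - calibration$zero_offset) / calibration$adu_per_photon
  if (is.finite(floor)) ph[ph < floor] <- floor
  ph
}
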