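# Poisson crystal-loading statistics. Crystals settle into chip pores
# independently, so the per-pore occupancy k is Poisson with mean lambda:
# a shot on a pore is a hit when k >= 1, a clean single-crystal hit when
# k = 1. The single-hit rate lambda*exp(-lambda) peaks at lambda = 1, where
# it equals 1/e (~37%) and the total hit rate is 1 - 1/e (~63%).

.check_lambda <- function(lam) {
  if (any(lam < 0)) stop("lambda must be non-negative")
}

#' Total hit rate under Poisson loading
#'
#' Probability that a probed pore holds at least one crystal.
#'
#' @param lam mean crystals per probed pore (vectorised).
#' @return `1 - exp(-lam)`.
#' @export
total_hit_rate <- function(lam) {
  .check_lambda(lam)
  -expm1(-lam)
}

#' Single-crystal hit rate under Poisson loading
#'
#' Probability that a probed pore holds exactly one crystal,
#' `lam * exp(-lam)`; maximised at `lam = 1` with value `exp(-1)`.
#'
#' @inheritParams total_hit_rate
#' @export
single_hit_rate <- function(lam) {
  .check_lambda(lam)
  lam * exp(-lam)
}

#' Multi-crystal hit rate under Poisson loading
#'
#' Probability of two or more crystals in a probed pore,
#' `1 - exp(-lam) - lam exp(-lam)`.
#'
#' @inheritParams total_hit_rate
#' @export
multi_hit_rate <- function(lam) {
  .check_lambda(lam)
  -expm1(-lam) - lam * exp(-lam)
}

#' Invert an observed total hit rate to a loading density
#'
#' @param hit_rate observed fraction of shots that are hits, in `[0, 1)`.
#' @return `lam = -log(1 - hit_rate)`, so that
#'   `total_hit_rate(lam) == hit_rate`.
#' @examples
#' lambda_from_hit_rate(0.38)  # ~0.478 crystals per probed pore
#' @export
lambda_from_hit_rate <- function(hit_rate) {
  if (any(hit_rate < 0) || any(hit_rate >= 1)) {
    stop("hit_rate must lie in [0, 1)")
  }
  -log1p(-hit_rate)
}

#' Loading density from deposition parameters
#'
#' Mean crystals per pore when a slurry of known concentration is spread
#' uniformly over the pores of a chip.
#'
#' @param concentration_per_ml crystals per ml of slurry.
#' @param volume_ul deposited volume in microlitres.
#' @param pore_count number of pores over which the crystals distribute.
#' @return `lam = concentration * volume / pore_count`.
#' @examples
#' lambda_from_loading(2.2e6, 20, 1e5)  # 0.44 crystals per pore
#' @export
lambda_from_loading <- function(concentration_per_ml, volume_ul, pore_count) {
  stopifnot(concentration_per_ml >= 0, volume_ul >= 0)
  if (pore_count <= 0) stop("pore_count must be positive")
  concentration_per_ml * (volume_ul * 1e-3) / pore_count
}

#' Summary table of Poisson hit rates
#'
#' @inheritParams total_hit_rate
#' @return `data.frame` with `lambda`, `total`, `single`, `multi` columns.
#' @export
hit_rate_table <- function(lam) {
  .check_lambda(lam)
  data.frame(lambda = lam,
             total = total_hit_rate(lam),
             single = single_hit_rate(lam),
             multi = multi_hit_rate(lam))
}
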