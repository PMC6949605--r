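# JSON reports for machine consumption of budget and scan-analysis results.

#' Write a photon-budget JSON report
#'
#' @param budget result of [background_budget()].
#' @param path output file.
#' @export
write_budget_report <- function(budget, path) {
  rep <- list(mode = attr(budget, "mode"),
              total_scattered_photons = attr(budget, "total"),
              dominant = attr(budget, "dominant"),
              components = budget)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Write a scan-analysis JSON report
#'
#' Summarises an analysed shot table: shot and hit counts, hit rate, the
#' inferred Poisson loading density, population counts and median-intensity
#' quartiles, plus the gain calibration when attached.
#'
#' @param shots analysed shot table from [analyze_scan()].
#' @param path output file.
#' @export
write_analysis_report <- function(shots, path) {
  hr <- mean(shots$is_hit)
  cal <- attr(shots, "calibration")
  rep <- list(
    n_shots = nrow(shots),
    n_hits = sum(shots$is_hit),
    hit_rate = hr,
    poisson_lambda = if (hr < 1) lambda_from_hit_rate(hr) else NA,
    populations = as.list(table(shots$population)),
    median_pp_quartiles = as.list(stats::quantile(shots$median_pp,
                                                  c(0.25, 0.5, 0.75))),
    gain = if (!is.null(cal)) list(adu_per_photon = cal$adu_per_photon,
                                   zero_offset = cal$zero_offset,
                                   fit_quality = cal$fit_quality))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
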