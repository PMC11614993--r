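#' Run the full analysis on an inversion-recovery experiment
#'
#' Convenience wrapper chaining the pipeline stages: process every FID with
#' one recipe, freeze peak positions on the first spectrum, extract
#' per-peak recovery series with SNR-based errors, optionally correct for
#' sample deterioration using the repeated reference delay, and fit the
#' mono-exponential recovery per peak.
#'
#' @param experiment An `ir_experiment` from [simulate_experiment()] (or
#'   read back via [read_experiment()]).
#' @param recipe A [processing_recipe()] or preset name.
#' @param windows Named search windows; default derived from the
#'   experiment's resonances via [peak_windows()].
#' @param noise_region Noise region in ppm.
#' @param drift_correct Correct deterioration when at least two reference
#'   points are present.
#' @param weighted Weight the recovery fits by `1/error^2`.
#' @return List with `peak_table`, `series` (all peaks), `drift` (per-peak
#'   `drift_fit` or `NULL`) and `fits` (named list of `recovery_fit`).
#' @export
#' @examples
#' ex <- simulate_experiment("in_cell", acq_config(), "nine_delay")
#' res <- analyze_experiment(ex, "lb1_trunc")
#' res$fits[["T4/T22/T18"]]
analyze_experiment <- function(experiment,
                               recipe = recipe_preset("lb1_trunc"),
                               windows = NULL,
                               noise_region = c(15, 16),
                               drift_correct = TRUE,
                               weighted = TRUE) {
  stopifnot(inherits(experiment, "ir_experiment"))
  if (is.null(windows)) windows <- peak_windows(experiment$resonances)
  spectra <- process_experiment(experiment, recipe)
  pt <- locate_peaks(spectra[[1]], windows, noise_region)
  series <- extract_series(spectra, pt, noise_region)
  per_peak <- split_series(series)
  drifts <- list()
  fits <- list()
  for (id in names(per_peak)) {
    s <- per_peak[[id]]
    if (drift_correct && sum(s$is_reference) >= 2) {
      d <- fit_drift(s)
      s <- correct_deterioration(s, d)
      drifts[[id]] <- d
    } else {
      drifts[id] <- list(NULL)
    }
    fits[[id]] <- fit_recovery(s, weighted = weighted)
  }
  list(peak_table = pt, series = series, drift = drifts, fits = fits)
}
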