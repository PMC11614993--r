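#' Acquisition configuration for 1D simulations
#'
#' Collects the spectrometer parameters needed to lay out a complex 1D FID:
#' base frequency, spectral width, carrier position, number of complex
#' points and the per-point noise level. The dwell time is
#' `1 / (spectral_width * spectrometer_freq)` seconds and the acquisition
#' time `n_points` times that.
#'
#' Defaults follow a 600.16 MHz instrument with a 22.04 ppm window centred
#' on the imino region (13.5 ppm carrier) and 2048 complex points
#' (acquisition time approximately 155 ms).
#'
#' @param spectrometer_freq Proton base frequency (MHz).
#' @param spectral_width Spectral window (ppm).
#' @param carrier Carrier position (ppm); centre of the ppm axis.
#' @param n_points Number of complex time-domain points; even, at least 2.
#' @param noise_sigma Standard deviation of the iid Gaussian noise added
#'   independently to the real and imaginary channel of every point
#'   (amplitude units). See [noise_sigma_for_snr()] to calibrate this
#'   against a target spectrum signal-to-noise ratio.
#' @param seed Optional integer seed; [simulate_experiment()] seeds the RNG
#'   with it once per experiment so a fixed seed gives bit-identical series.
#' @return An object of class `acq_config`.
#' @export
acq_config <- function(spectrometer_freq = 600.16, spectral_width = 22.04,
                       carrier = 13.5, n_points = 2048,
                       noise_sigma = 0, seed = NULL) {
  if (n_points < 2 || n_points %% 2 != 0)
    stop("'n_points' must be even and >= 2")
  if (spectral_width <= 0) stop("'spectral_width' must be > 0")
  if (noise_sigma < 0) stop("'noise_sigma' must be >= 0")
  structure(list(spectrometer_freq = spectrometer_freq,
                 spectral_width = spectral_width,
                 carrier = carrier, n_points = n_points,
                 noise_sigma = noise_sigma, seed = seed),
            class = "acq_config")
}

#' Dwell time and acquisition time of a configuration
#'
#' @param acq An [acq_config()].
#' @return `acq_dwell`: sampling interval in seconds.
#' @export
acq_dwell <- function(acq) {
  1 / (acq$spectral_width * acq$spectrometer_freq)
}

#' @rdname acq_dwell
#' @return `acq_time`: total acquisition time in seconds.
#' @export
acq_time <- function(acq) acq$n_points * acq_dwell(acq)

#' Recovery-delay schedule of an inversion-recovery experiment
#'
#' One technical replicate measures one spectrum per recovery delay tau.
#' A reference delay (here 0.320 ms) is interleaved and re-measured so that
#' sample deterioration over wall-clock time can be tracked by a linear fit
#' through the repeated reference intensities.
#'
#' Preset schedules (pass the name as `delays`):
#' \describe{
#'   \item{`"nine_delay"`}{0.320, 150, 300, 600, 1200, 0.320, 225, 450,
#'     900 ms -- the standard series.}
#'   \item{`"nine_delay_short"`}{0.320, 15, 50, 250, 900, 0.320, 7.5, 75,
#'     4 ms -- the short-delay series used once the in-cell relaxation
#'     turned out faster than anticipated.}
#' }
#'
#' Start times default to back-to-back experiments of
#' `n_scans * (base_recovery + tau)` each (minutes), i.e. roughly 17 min for
#' the shortest and 37 min for the longest delay at 1024 scans.
#'
#' @param delays Numeric vector of recovery delays (ms), or a preset name.
#' @param is_reference Logical flags marking reference entries. Default:
#'   every delay value that occurs more than once is a reference.
#' @param start_times Wall-clock start of each delay's experiment (min),
#'   strictly increasing. Default as described above.
#' @param n_scans,base_recovery Used only to derive default start times:
#'   scans per experiment and per-scan non-tau recovery (ms).
#' @return An object of class `delay_schedule`.
#' @export
#' @examples
#' sched <- delay_schedule("nine_delay")
#' sum(sched$is_reference)  # 2
delay_schedule <- function(delays, is_reference = NULL, start_times = NULL,
                           n_scans = 1024, base_recovery = 968.5) {
  if (is.character(delays)) {
    delays <- switch(match.arg(delays, c("nine_delay", "nine_delay_short")),
      nine_delay = c(0.320, 150, 300, 600, 1200, 0.320, 225, 450, 900),
      nine_delay_short = c(0.320, 15, 50, 250, 900, 0.320, 7.5, 75, 4))
  }
  if (any(delays <= 0)) stop("all delays must be > 0")
  if (is.null(is_reference))
    is_reference <- delays %in% unique(delays[duplicated(delays)])
  if (length(is_reference) != length(delays))
    stop("'is_reference' must match 'delays' in length")
  if (is.null(start_times)) {
    dur_min <- n_scans * (base_recovery + delays) / 1000 / 60
    start_times <- c(0, cumsum(dur_min[-length(dur_min)]))
  }
  if (length(start_times) != length(delays) || any(diff(start_times) <= 0))
    stop("'start_times' must be strictly increasing, one per delay")
  structure(list(delays = delays, is_reference = as.logical(is_reference),
                 start_times = start_times),
            class = "delay_schedule")
}

#' Linear sample-deterioration model
#'
#' Cell death and sample degradation scale all signal down over wall-clock
#' time. The model is multiplicative: every amplitude is scaled by
#' `1 + relative_slope * (t - reference_time)`. The factor must stay
#' positive over the schedule it is applied to.
#'
#' @param relative_slope Fractional intensity change per minute. The default
#'   0 means no drift; a typical in-cell value is about `-15%` over 4 h,
#'   i.e. `-0.15/240` per min (viability dropping from ~84% to ~69%).
#' @param reference_time Time (min) at which the factor equals 1.
#' @return An object of class `drift_model`.
#' @export
drift_model <- function(relative_slope = 0, reference_time = 0) {
  structure(list(relative_slope = relative_slope,
                 reference_time = reference_time),
            class = "drift_model")
}

#' @rdname drift_model
#' @param drift A `drift_model`.
#' @param t Time(s) in minutes.
#' @return `drift_factor`: the multiplicative factor at `t`.
#' @export
drift_factor <- function(drift, t) {
  1 + drift$relative_slope * (t - drift$reference_time)
}
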