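#' Locate peaks in the first spectrum of a series
#'
#' The chemical shift of each peak is frozen to the position of the
#' absolute-intensity extremum inside its search window, as observed in the
#' first spectrum of the series (typically the shortest, inverted delay);
#' all later spectra are read out at that fixed shift. Freezing the shift
#' avoids chasing noise-driven apparent maxima at low SNR.
#'
#' A window whose extremum does not rise above three times the RMS noise of
#' the spectrum's noise region is flagged as unlocatable (`located = FALSE`)
#' but still reported.
#'
#' @param spectrum The first `nmr_spectrum` of the series.
#' @param windows Named list `peak_id -> c(low_ppm, high_ppm)`; windows must
#'   lie within the axis and not overlap.
#' @param noise_region ppm interval used for the noise floor
#'   (default 15--16 ppm, a signal-free region upfield of the iminos).
#' @return A data frame (`peak_table`) with columns `peak_id`,
#'   `fixed_shift`, `window_lo`, `window_hi`, `height`, `located`.
#' @export
locate_peaks <- function(spectrum, windows, noise_region = c(15, 16)) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  if (length(windows) == 0)
    return(data.frame(peak_id = character(), fixed_shift = numeric(),
                      window_lo = numeric(), window_hi = numeric(),
                      height = numeric(), located = logical(),
                      stringsAsFactors = FALSE))
  if (is.null(names(windows)) || any(!nzchar(names(windows))))
    stop("'windows' must be a named list")
  rng <- range(spectrum$ppm)
  win <- t(vapply(windows, function(w) sort(as.numeric(w)), numeric(2)))
  if (any(win[, 1] < rng[1]) || any(win[, 2] > rng[2]))
    stop("search windows must lie within the spectrum axis")
  o <- order(win[, 1])
  if (nrow(win) > 1 && any(win[o, 1][-1] < win[o, 2][-nrow(win)]))
    stop("search windows must not overlap")
  floor_rms <- tryCatch(rms_noise(spectrum, noise_region),
                        error = function(e) 0)
  res <- lapply(seq_len(nrow(win)), function(i) {
    idx <- which(spectrum$ppm >= win[i, 1] & spectrum$ppm <= win[i, 2])
    if (length(idx) == 0) stop("empty search window")
    j <- idx[which.max(abs(spectrum$intensities[idx]))]
    h <- abs(spectrum$intensities[j])
    data.frame(peak_id = rownames(win)[i], fixed_shift = spectrum$ppm[j],
               window_lo = win[i, 1], window_hi = win[i, 2], height = h,
               located = if (floor_rms > 0) h > 3 * floor_rms else h > 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Default search windows from a resonance list
#'
#' @param resonances Resonance list or preset name.
#' @param half_width Half window width in ppm (default 0.12, narrow enough
#'   that the preset peaks, at least 0.25 ppm apart, never overlap).
#' @return Named list of `c(lo, hi)` windows keyed by peak label.
#' @export
peak_windows <- function(resonances, half_width = 0.12) {
  if (is.character(resonances)) resonances <- resonance_presets(resonances)
  w <- lapply(resonances, function(r) r$shift + c(-1, 1) * half_width)
  names(w) <- vapply(resonances, `[[`, character(1), "label")
  w
}

#' RMS noise of a spectrum region
#'
#' Standard deviation of the intensities in a peak-free region after
#' subtracting the region mean. Subtracting the mean first makes the
#' estimate insensitive to a constant baseline offset, which would
#' otherwise inflate the apparent noise and falsify every SNR.
#'
#' @param spectrum An `nmr_spectrum`.
#' @param region `c(low_ppm, high_ppm)`; must contain at least 16 points.
#' @return RMS noise (amplitude units).
#' @export
rms_noise <- function(spectrum, region = c(15, 16)) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  region <- sort(region)
  x <- spectrum$intensities[spectrum$ppm >= region[1] & spectrum$ppm <= region[2]]
  if (length(x) < 16)
    stop("noise region must contain at least 16 points")
  stats::sd(x)
}

#' Signal-to-noise ratio of a peak
#'
#' `SNR = I / (2 * rms_noise)`, the spectrometer-software (SINO-style)
#' convention. Under this convention the standard error of a peak
#' intensity, `I / (2 * SNR)`, reduces exactly to the RMS noise of the
#' spectrum.
#'
#' @param spectrum An `nmr_spectrum`.
#' @param fixed_shift Chemical shift (ppm) read at the nearest grid point.
#' @param region Noise region, see [rms_noise()].
#' @return The (signed) SNR; `Inf` for a noiseless spectrum.
#' @export
spectrum_snr <- function(spectrum, fixed_shift, region = c(15, 16)) {
  i <- which.min(abs(spectrum$ppm - fixed_shift))
  rms <- rms_noise(spectrum, region)
  if (rms == 0) return(Inf)
  spectrum$intensities[i] / (2 * rms)
}

#' Standard error of a peak intensity from its SNR
#'
#' `error = I / (2 * SNR)`; with the [spectrum_snr()] convention this is
#' the RMS noise of the spectrum.
#'
#' @param intensity Peak intensity (amplitude units).
#' @param snr Signal-to-noise ratio, positive.
#' @return Standard error (same units).
#' @export
intensity_error <- function(intensity, snr) {
  if (any(snr <= 0)) stop("'snr' must be > 0")
  intensity / (2 * snr)
}

#' Extract recovery series from a processed experiment
#'
#' Reads every spectrum at the frozen chemical shift of each located peak
#' (nearest grid point, no interpolation) and attaches the per-spectrum
#' standard error `I/(2*SNR)`, i.e. the RMS noise of that spectrum. A
#' shift-drift diagnostic (distance between the per-spectrum argmax inside
#' the window and the frozen shift) is reported but never used to re-pick
#' the peak position.
#'
#' @param spectra List of `nmr_spectrum` sharing one axis, with `tau`,
#'   `start_time` and `is_reference` metadata.
#' @param peak_table Output of [locate_peaks()].
#' @param noise_region Noise region, see [rms_noise()].
#' @return A `recovery_series` data frame with columns `peak_id`, `tau`,
#'   `intensity`, `error`, `start_time`, `is_reference`, `shift_drift`.
#' @export
extract_series <- function(spectra, peak_table, noise_region = c(15, 16)) {
  stopifnot(length(spectra) >= 1)
  axis <- spectra[[1]]$ppm
  same <- vapply(spectra, function(s)
    length(s$ppm) == length(axis) && max(abs(s$ppm - axis)) < 1e-9, logical(1))
  if (!all(same)) stop("all spectra must share one ppm axis")
  if (nrow(peak_table) == 0)
    return(structure(data.frame(peak_id = character(), tau = numeric(),
                                intensity = numeric(), error = numeric(),
                                start_time = numeric(), is_reference = logical(),
                                shift_drift = numeric(), stringsAsFactors = FALSE),
                     class = c("recovery_series", "data.frame")))
  rows <- lapply(seq_along(spectra), function(k) {
    sp <- spectra[[k]]
    rms <- rms_noise(sp, noise_region)
    do.call(rbind, lapply(seq_len(nrow(peak_table)), function(i) {
      j <- which.min(abs(axis - peak_table$fixed_shift[i]))
      widx <- which(axis >= peak_table$window_lo[i] &
                    axis <= peak_table$window_hi[i])
      jmax <- widx[which.max(abs(sp$intensities[widx]))]
      data.frame(peak_id = peak_table$peak_id[i],
                 tau = sp$meta$tau,
                 intensity = sp$intensities[j],
                 error = rms,
                 start_time = if (is.null(sp$meta$start_time)) NA_real_ else sp$meta$start_time,
                 is_reference = isTRUE(sp$meta$is_reference),
                 shift_drift = abs(axis[jmax] - peak_table$fixed_shift[i]),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$peak_id, out$start_time), ]
  rownames(out) <- NULL
  class(out) <- c("recovery_series", "data.frame")
  out
}

#' Split a recovery series by peak
#'
#' @param series A `recovery_series` data frame.
#' @return Named list of per-peak `recovery_series`.
#' @export
split_series <- function(series) {
  out <- split(as.data.frame(series), series$peak_id)
  lapply(out, function(d) {
    rownames(d) <- NULL
    class(d) <- c("recovery_series", "data.frame")
    d
  })
}
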