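#' Write a simulated experiment to disk
#'
#' Directory layout: one columnar text file per FID (`fid_###.txt` with
#' columns index, real, imaginary) plus `metadata.json` holding the delay
#' schedule, start times, reference flags and acquisition parameters.
#' With `bundle = TRUE` everything is written to a single JSON file
#' instead.
#'
#' @param experiment An `ir_experiment`.
#' @param path Output directory (or file path when `bundle = TRUE`).
#' @param bundle Write a single JSON bundle instead of a directory.
#' @return `path`, invisibly.
#' @export
write_experiment <- function(experiment, path, bundle = FALSE) {
  stopifnot(inherits(experiment, "ir_experiment"))
  acq <- experiment$acq
  meta <- list(
    acq = list(spectrometer_freq = acq$spectrometer_freq,
               spectral_width = acq$spectral_width, carrier = acq$carrier,
               n_points = acq$n_points, noise_sigma = acq$noise_sigma),
    delays = experiment$schedule$delays,
    is_reference = experiment$schedule$is_reference,
    start_times = experiment$schedule$start_times)
  if (bundle) {
    meta$fids <- lapply(experiment$fids, function(f)
      list(real = Re(f$points), imaginary = Im(f$points)))
    jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta$files <- sprintf("fid_%03d.txt", seq_along(experiment$fids))
  for (i in seq_along(experiment$fids)) {
    f <- experiment$fids[[i]]
    utils::write.table(
      data.frame(index = seq_along(f$points) - 1,
                 real = Re(f$points), imaginary = Im(f$points)),
      file.path(path, meta$files[i]),
      row.names = FALSE, quote = FALSE, sep = "\t")
  }
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an experiment written by [write_experiment()]
#'
#' @param path Directory (or JSON bundle file).
#' @return An `ir_experiment` (without resonance ground truth).
#' @export
read_experiment <- function(path) {
  meta_file <- if (dir.exists(path)) file.path(path, "metadata.json") else path
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  acq <- acq_config(spectrometer_freq = meta$acq$spectrometer_freq,
                    spectral_width = meta$acq$spectral_width,
                    carrier = meta$acq$carrier,
                    n_points = meta$acq$n_points,
                    noise_sigma = meta$acq$noise_sigma)
  sched <- delay_schedule(meta$delays, meta$is_reference, meta$start_times)
  dw <- acq_dwell(acq)
  read_one <- function(i) {
    if (dir.exists(path)) {
      d <- utils::read.table(file.path(path, meta$files[i]), header = TRUE)
      pts <- complex(real = d$real, imaginary = d$imaginary)
    } else {
      pts <- complex(real = meta$fids$real[[i]],
                     imaginary = meta$fids$imaginary[[i]])
    }
    f <- new_fid(pts, dw, meta = list(tau = sched$delays[i],
                                      start_time = sched$start_times[i],
                                      is_reference = sched$is_reference[i],
                                      acq = acq))
    f
  }
  fids <- lapply(seq_along(sched$delays), read_one)
  structure(list(fids = fids, schedule = sched, acq = acq,
                 resonances = NULL, drift = NULL),
            class = "ir_experiment")
}

#' Write / read a recovery series as tab-separated text
#'
#' Columns: `peak_id`, `tau_ms`, `intensity`, `error`, `start_time_min`,
#' `is_reference`.
#'
#' @param series A `recovery_series`.
#' @param path Output file.
#' @return `path` (write) or the `recovery_series` (read).
#' @export
write_series <- function(series, path) {
  out <- data.frame(peak_id = series$peak_id, tau_ms = series$tau,
                    intensity = series$intensity, error = series$error,
                    start_time_min = series$start_time,
                    is_reference = series$is_reference)
  utils::write.table(out, path, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  out <- data.frame(peak_id = d$peak_id, tau = d$tau_ms,
                    intensity = d$intensity, error = d$error,
                    start_time = d$start_time_min,
                    is_reference = as.logical(d$is_reference),
                    stringsAsFactors = FALSE)
  class(out) <- c("recovery_series", "data.frame")
  out
}

#' Write a spectrum as two-column text with a provenance sidecar
#'
#' @param spectrum An `nmr_spectrum`.
#' @param path Output file (ppm, intensity); provenance goes to
#'   `<path>.provenance.json`.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  utils::write.table(data.frame(ppm = spectrum$ppm,
                                intensity = spectrum$intensities),
                     path, row.names = FALSE, quote = FALSE, sep = "\t")
  jsonlite::write_json(list(provenance = spectrum$provenance,
                            tau = spectrum$meta$tau,
                            start_time = spectrum$meta$start_time),
                       paste0(path, ".provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Best-effort reader for a Bruker TopSpin 1D dataset
#'
#' Reads the `acqus` parameter file (JCAMP-DX) and the binary `fid` of a
#' classic TopSpin 1D dataset directory and returns an `nmr_fid`. Supports
#' 32-bit integer and 64-bit float data (`DTYPA` 0/2), both byte orders
#' (`BYTORDA`), and sequential real/imaginary interleaving. Digital-filter
#' group delay is not corrected. This adapter is best-effort plumbing for
#' convenience; the package's own columnar format is the tested interchange
#' format.
#'
#' @param path Dataset directory containing `fid` and `acqus`.
#' @return An `nmr_fid` with acquisition metadata.
#' @export
read_bruker_fid <- function(path) {
  acqus_file <- file.path(path, "acqus")
  fid_file <- file.path(path, "fid")
  if (!file.exists(acqus_file) || !file.exists(fid_file))
    stop("'path' must contain 'acqus' and 'fid'")
  lines <- readLines(acqus_file, warn = FALSE)
  par1 <- function(name, default = NA_real_) {
    hit <- grep(sprintf("^##\\$%s=", name), lines, value = TRUE)
    if (length(hit) == 0) return(default)
    as.numeric(sub(sprintf("^##\\$%s= *", name), "", hit[1]))
  }
  td <- par1("TD")
  sw_h <- par1("SW_h")
  sfo1 <- par1("SFO1")
  o1 <- par1("O1")
  bytorda <- par1("BYTORDA", 0)
  dtypa <- par1("DTYPA", 0)
  if (!is.finite(td) || !is.finite(sw_h) || !is.finite(sfo1))
    stop("acqus lacks TD, SW_h or SFO1")
  endian <- if (bytorda == 1) "big" else "little"
  n_vals <- td  # TD counts real+imaginary values
  raw <- if (dtypa == 2)
    readBin(fid_file, "double", n = n_vals, size = 8, endian = endian)
  else
    readBin(fid_file, "integer", n = n_vals, size = 4, endian = endian)
  if (length(raw) < 2) stop("fid file shorter than TD")
  if (length(raw) %% 2 == 1) raw <- raw[-length(raw)]
  pts <- complex(real = raw[seq(1, length(raw), by = 2)],
                 imaginary = raw[seq(2, length(raw), by = 2)])
  acq <- acq_config(spectrometer_freq = sfo1, spectral_width = sw_h / sfo1,
                    carrier = if (is.finite(o1)) o1 / sfo1 else 0,
                    n_points = length(pts), noise_sigma = 0)
  new_fid(pts, 1 / sw_h, meta = list(acq = acq, source = path))
}
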