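# Shared fixtures and independent oracles, built in code at test time.

# Recovery-series data frame straight from the model (series-level fixture;
# noise sd in the same units as the intensities).
make_series <- function(selT1, A = 1, D = -2 * A,
                        delays = c(0.320, 150, 300, 600, 1200, 0.320, 225, 450, 900),
                        noise_sd = 0, start_times = seq_along(delays) * 20,
                        peak_id = "peak") {
  is_ref <- delays %in% unique(delays[duplicated(delays)])
  y <- A + D * exp(-delays / selT1)
  if (noise_sd > 0) y <- y + rnorm(length(y), 0, noise_sd)
  out <- data.frame(peak_id = peak_id, tau = delays, intensity = y,
                    error = if (noise_sd > 0) noise_sd else 0,
                    start_time = start_times, is_reference = is_ref,
                    stringsAsFactors = FALSE)
  class(out) <- c("recovery_series", "data.frame")
  out
}

# Brute-force oracle for the recovery fit: dense grid over selT1, with the
# linear parameters (A, D) solved exactly by weighted least squares at each
# grid point. Independent of the Levenberg-Marquardt path.
oracle_grid_fit <- function(series, T1_grid) {
  tau <- series$tau
  y <- series$intensity
  w <- if (all(series$error > 0)) 1 / series$error else rep(1, length(y))
  best <- c(T1 = NA_real_, rss = Inf)
  for (T1 in T1_grid) {
    X <- cbind(1, exp(-tau / T1)) * w
    yw <- y * w
    beta <- tryCatch(qr.solve(X, yw), error = function(e) NULL)
    if (is.null(beta)) next
    rss <- sum((yw - X %*% beta)^2)
    if (rss < best["rss"]) best <- c(T1 = T1, rss = rss)
  }
  best
}

# Grid-search oracle for the sensitivity optimum.
oracle_grid_trec <- function(selT1, overhead, step = 0.1) {
  grid <- seq(step, 20 * selT1, by = step)
  grid[which.max(sofast_sensitivity(grid, selT1, overhead))]
}

# Minimal spectrum object for extraction-level tests.
make_spectrum <- function(ppm, intensities, tau = 1, start_time = 0,
                          is_reference = FALSE) {
  structure(list(intensities = intensities, ppm = ppm,
                 provenance = "synthetic",
                 meta = list(tau = tau, start_time = start_time,
                             is_reference = is_reference)),
            class = "nmr_spectrum")
}
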