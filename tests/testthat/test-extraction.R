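acq0 <- acq_config(noise_sigma = 0)

test_that("peak positions are frozen to the first spectrum's extrema", {
  sp <- to_spectrum(simulate_fid(list(resonance(13.4, 10, selT1 = 84)),
                                 acq0, tau = 1e4))
  step <- abs(diff(sp$ppm[1:2]))
  pt <- locate_peaks(sp, list(T = c(13, 14)))
  expect_equal(pt$fixed_shift, 13.4, tolerance = step)
  expect_true(pt$located)
  # inverted (negative) peaks are located by |intensity|
  spi <- to_spectrum(simulate_fid(list(resonance(13.4, 10, A = 1, D = -2,
                                                 selT1 = 84)), acq0, tau = 0.32))
  pti <- locate_peaks(spi, list(T = c(13, 14)))
  expect_equal(pti$fixed_shift, pt$fixed_shift, tolerance = step)

  expect_error(locate_peaks(sp, list(T = c(30, 31))), "within")
  expect_error(locate_peaks(sp, list(a = c(13, 14), b = c(13.5, 14.5))),
               "overlap")
  expect_identical(locate_peaks(sp, list(T = c(13, 14))), pt)  # deterministic
  expect_equal(nrow(locate_peaks(sp, list())), 0)
})

test_that("RMS noise estimation is unbiased and baseline-insensitive", {
  ppm <- seq(20, 2, length.out = 10000)
  # constant region has zero RMS
  expect_equal(rms_noise(make_spectrum(ppm, rep(3, 10000)), c(15, 16)), 0)
  set.seed(42)
  noise <- rnorm(10000, 0, 0.7)
  sp <- make_spectrum(ppm, noise)
  est <- rms_noise(sp, c(15, 16))
  expect_equal(est, 0.7, tolerance = 0.05)
  # a systematic baseline offset must not inflate the estimate
  sp_off <- make_spectrum(ppm, noise + 100)
  expect_equal(rms_noise(sp_off, c(15, 16)), est, tolerance = 1e-12)
  expect_error(rms_noise(sp, c(15, 15.001)), "16 points")
})

test_that("SNR follows the SINO convention and the error formula closes on it", {
  ppm <- seq(20, 2, length.out = 1000)
  ints <- rep(0, 1000)
  ints[ppm >= 15 & ppm <= 16] <- rep(c(-0.5, 0.5), length.out = sum(ppm >= 15 & ppm <= 16))
  sp <- make_spectrum(ppm, ints)
  rms <- rms_noise(sp, c(15, 16))
  sp$intensities[which.min(abs(ppm - 13.4))] <- 10 * 2 * rms
  expect_equal(spectrum_snr(sp, 13.4), 10, tolerance = 1e-9)
  # scale invariance
  sp3 <- sp; sp3$intensities <- 3 * sp3$intensities
  expect_equal(spectrum_snr(sp3, 13.4), spectrum_snr(sp, 13.4))
  # noiseless spectra report the infinite-SNR sentinel
  expect_equal(spectrum_snr(make_spectrum(ppm, rep(0, 1000)), 13.4), Inf)

  expect_equal(intensity_error(5, 10), 0.25)
  expect_equal(intensity_error(10, 10), 0.5)  # equals the rms noise
  expect_error(intensity_error(5, 0))
})

test_that("doubling the injected noise halves the measured SNR", {
  sig <- noise_sigma_for_snr("in_cell", acq_config(), snr = 10)
  snr_at <- function(mult, seeds = 1:3) {
    mean(vapply(seeds, function(s) {
      ex <- simulate_experiment("in_cell",
                                acq_config(noise_sigma = mult * sig, seed = s),
                                "nine_delay")
      spectrum_snr(process_experiment(ex, "lb1_trunc")[[5]], 13.4)
    }, numeric(1)))
  }
  expect_equal(snr_at(2) / snr_at(1), 0.5, tolerance = 0.2)
})

test_that("extracted series reproduce the recovery law up to a common scale", {
  r <- resonance(13.4, 25, A = 3, D = -6, selT1 = 84, label = "T")
  ex <- simulate_experiment(list(r), acq0, "nine_delay")
  spectra <- process_experiment(ex, "lb1_trunc")
  pt <- locate_peaks(spectra[[1]], list(T = c(13, 13.8)))
  series <- extract_series(spectra, pt)
  expect_equal(nrow(series), 9)
  expect_equal(sum(series$is_reference), 2)
  # noiseless: only far Lorentzian tails reach the noise region, so the
  # reported errors are negligible against the peak intensities
  expect_lt(max(series$error), 1e-3 * max(abs(series$intensity)))
  amp <- 3 - 6 * exp(-series$tau / 84)
  scale <- series$intensity[which.max(abs(amp))] / amp[which.max(abs(amp))]
  expect_lt(max(abs(series$intensity - scale * amp) / max(abs(series$intensity))),
            1e-3)
  # empty peak table -> empty series
  expect_equal(nrow(extract_series(spectra, pt[0, ])), 0)
  # axis mismatch is rejected
  other <- to_spectrum(simulate_fid(list(r), acq0, tau = 10), zero_fill = 2048)
  expect_error(extract_series(list(spectra[[1]], other), pt), "axis")
})

test_that("reported per-point errors track the injected spectrum noise", {
  sig <- noise_sigma_for_snr("in_cell", acq_config(), snr = 10)
  acqn <- acq_config(noise_sigma = sig, seed = 5)
  ex <- simulate_experiment("in_cell", acqn, "nine_delay")
  spectra <- process_experiment(ex, "lb1_trunc")
  pt <- locate_peaks(spectra[[1]], peak_windows("in_cell"))
  series <- extract_series(spectra, pt)
  # the error column is the per-spectrum rms noise; its average should sit
  # near the analytic propagation of sigma through the recipe window
  w <- exp(-pi * 1 * (0:511) * acq_dwell(acqn))
  expect_equal(mean(series$error), sig * sqrt(sum(w^2)), tolerance = 0.1)
  # errors scale linearly with the injected noise sd
  acq2 <- acq_config(noise_sigma = 2 * sig, seed = 5)
  ex2 <- simulate_experiment("in_cell", acq2, "nine_delay")
  s2 <- extract_series(process_experiment(ex2, "lb1_trunc"), pt)
  expect_equal(mean(s2$error) / mean(series$error), 2, tolerance = 0.15)
})
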