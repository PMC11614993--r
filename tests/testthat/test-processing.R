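acq0 <- acq_config(noise_sigma = 0)

test_that("truncation keeps the leading points and rejects degenerate sizes", {
  fid <- simulate_fid(list(resonance(13.4, 25, selT1 = 84)), acq0, tau = 50)
  tr <- truncate_fid(fid, 512)
  expect_length(tr$points, 512)
  expect_identical(tr$points, fid$points[1:512])
  expect_identical(truncate_fid(fid, length(fid$points))$points, fid$points)
  expect_error(truncate_fid(fid, 1))
  expect_error(truncate_fid(fid, 5000))
})

test_that("exponential apodization applies the EM window pointwise", {
  fid <- new_fid(rep(1 + 0i, 4), dwell = 0.5,
                 meta = list(acq = acq_config(n_points = 4)))
  ap <- apodize_exponential(fid, lb = 1)
  # point k = 2 sits at t = 1 s: multiplier exp(-pi) ~ 0.0432
  expect_equal(Re(ap$points[3]), exp(-pi), tolerance = 1e-12)
  expect_equal(Re(ap$points[1]), 1)
  expect_identical(apodize_exponential(fid, 0)$points, fid$points)
  expect_error(apodize_exponential(fid, -1))
})

test_that("line broadening adds to the Lorentzian width (convolution theorem)", {
  acq <- acq_config(n_points = 8192, noise_sigma = 0)
  fid <- simulate_fid(list(resonance(13.5, 8, selT1 = 100)), acq, tau = 1e4)
  measure_fwhm <- function(sp) {
    half <- max(sp$intensities) / 2
    above <- which(sp$intensities >= half)
    # linear interpolation at the two crossings
    lo <- min(above); hi <- max(above)
    interp <- function(i1, i2) {
      f <- (half - sp$intensities[i1]) / (sp$intensities[i2] - sp$intensities[i1])
      sp$ppm[i1] + f * (sp$ppm[i2] - sp$ppm[i1])
    }
    abs(interp(lo, lo - 1) - interp(hi, hi + 1)) * acq$spectrometer_freq
  }
  sp <- to_spectrum(apodize_exponential(fid, 8), zero_fill = 65536)
  expect_equal(measure_fwhm(sp), 16, tolerance = 0.05)
})

test_that("apodization never increases the peak height of a decaying signal", {
  fid <- simulate_fid(list(resonance(13.4, 10, selT1 = 84)), acq0, tau = 1e4)
  for (lb in c(0.5, 2, 15)) {
    expect_lte(max(to_spectrum(apodize_exponential(fid, lb))$intensities),
               max(to_spectrum(fid)$intensities))
  }
})

test_that("linear prediction continues damped exponentials analytically", {
  # single damped complex exponential, 2 coefficients: exact continuation
  dw <- 1e-4
  n <- 64
  z <- exp(complex(real = -pi * 20 * dw, imaginary = 2 * pi * 500 * dw))
  x <- z^(0:(n - 1))
  fid <- new_fid(x, dw, meta = list(acq = acq_config(n_points = n)))
  ext <- linear_predict(fid, n_coefficients = 2, n_output = 256)
  truth <- z^(0:255)
  expect_identical(ext$points[1:n], x)  # existing points untouched
  expect_lt(max(Mod(ext$points - truth) / Mod(truth)), 1e-6)

  # all-zero FID falls back to zero-fill
  zfid <- new_fid(rep(0 + 0i, 32), dw, meta = list(acq = acq_config(n_points = 32)))
  expect_warning(zext <- linear_predict(zfid, 2, 64), "rank deficient")
  expect_true(all(zext$points == 0))
  expect_length(zext$points, 64)

  expect_error(linear_predict(fid, 64, 256))   # too many coefficients
  expect_error(linear_predict(fid, 2, 10))     # output shorter than input
})

test_that("16-coefficient prediction restores peak positions of truncated multiplets", {
  # seven damped exponentials (the in vitro resonance set)
  acq <- acq_config(noise_sigma = 0)
  fid <- simulate_fid(resonance_presets("in_vitro"), acq, tau = 1e4)
  full <- to_spectrum(fid, zero_fill = 4096)
  tr <- truncate_fid(fid, 512)
  lp <- to_spectrum(linear_predict(tr, 16, 2048), zero_fill = 4096)
  step <- abs(diff(full$ppm[1:2]))
  for (w in peak_windows("in_vitro")) {
    idx <- which(full$ppm >= w[1] & full$ppm <= w[2])
    p_full <- full$ppm[idx[which.max(full$intensities[idx])]]
    p_lp <- lp$ppm[idx[which.max(lp$intensities[idx])]]
    expect_lte(abs(p_full - p_lp), step + 1e-12)
  }
})

test_that("the spectrum axis follows the carrier-centred ppm convention", {
  acq <- acq_config(spectral_width = 22.04, carrier = 13.5, noise_sigma = 0)
  r <- resonance(14.5, 5, selT1 = 100)
  sp <- to_spectrum(simulate_fid(list(r), acq, tau = 1e4))
  step <- abs(diff(sp$ppm[1:2]))
  expect_equal(sp$ppm[which.max(sp$intensities)], 14.5, tolerance = step)
  expect_true(all(diff(sp$ppm) < 0))  # descending axis
  expect_equal(sp$ppm[1], 13.5 + 22.04 / 2, tolerance = 2 * step)
  expect_equal(sp$ppm[length(sp$ppm)], 13.5 - 22.04 / 2, tolerance = 2 * step)

  # zero in, zero out
  zfid <- new_fid(rep(0 + 0i, 64), acq_dwell(acq), meta = list(acq = acq))
  expect_true(all(to_spectrum(zfid)$intensities == 0))

  # acquisition metadata is required for the ppm conversion
  bare <- new_fid(rep(1 + 0i, 64), 1e-4)
  expect_error(to_spectrum(bare), "acquisition")
})

test_that("Fourier processing is linear in the input FID", {
  r1 <- resonance(13.4, 25, A = 1, D = -2, selT1 = 84)
  r2 <- resonance(12.2, 25, A = 2, D = -4, selT1 = 101)
  f1 <- simulate_fid(list(r1), acq0, tau = 50)
  f2 <- simulate_fid(list(r2), acq0, tau = 50)
  fsum <- simulate_fid(list(r1, r2), acq0, tau = 50)
  s1 <- to_spectrum(f1); s2 <- to_spectrum(f2); ss <- to_spectrum(fsum)
  expect_equal(ss$intensities, s1$intensities + s2$intensities,
               tolerance = 1e-10)
})

test_that("the three standard recipes carry the published parameters", {
  r1 <- recipe_preset("lb1_trunc")
  expect_equal(r1$lb, 1); expect_equal(r1$td_eff, 512)
  expect_equal(r1$lp_coefficients, 0)
  r2 <- recipe_preset("lb1_trunc_lp")
  expect_equal(r2$lp_coefficients, 16); expect_equal(r2$lp_output, 8192)
  r3 <- recipe_preset("lb15_full")
  expect_equal(r3$lb, 15); expect_null(r3$td_eff)
  fid <- simulate_fid(list(resonance(13.4, 25, selT1 = 84)), acq0, 50)
  sp <- run_recipe(fid, "lb1_trunc")
  expect_match(paste(sp$provenance, collapse = " "), "truncate\\(td_eff=512\\)")
  expect_match(paste(sp$provenance, collapse = " "), "em\\(lb=1\\)")
})

test_that("fitted relaxation times do not depend on the processing recipe", {
  # noiseless single resonance: every recipe must return the generating selT1
  r <- resonance(13.4, 25, A = 3, selT1 = 84, label = "T")
  ex <- simulate_experiment(list(r), acq0, "nine_delay")
  est <- vapply(c("lb1_trunc", "lb1_trunc_lp", "lb15_full"), function(rec) {
    analyze_experiment(ex, rec, windows = list(T = c(13, 13.8)))$fits$T$estimate[["selT1"]]
  }, numeric(1))
  expect_lt(max(est) / min(est) - 1, 0.01)
  expect_equal(unname(est["lb1_trunc"]), 84, tolerance = 1e-4)
})
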