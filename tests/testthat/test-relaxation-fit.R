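test_that("the deterioration line is the OLS fit through reference points", {
  s <- make_series(84, delays = c(0.32, 150, 300, 0.32), noise_sd = 0,
                   start_times = c(0, 20, 40, 240))
  # flat references: zero slope
  expect_equal(fit_drift(s)$slope, 0, tolerance = 1e-12)
  # two-point line: 1.0 at t=0 and 0.9 at t=240 -> -0.1/240 per min
  s2 <- s
  s2$intensity[s2$is_reference] <- c(1.0, 0.9)
  d <- fit_drift(s2)
  expect_equal(d$relative_slope, -0.1 / 240, tolerance = 1e-12)
  expect_equal(d$intercept, 1.0, tolerance = 1e-12)
  s3 <- s[!s$is_reference, ]
  expect_error(fit_drift(s3), "reference")
})

test_that("drift slope recovery is unbiased at in-cell noise levels", {
  # 10% decay over 4 h, SNR-10 noise on the references, 100 repeats
  set.seed(101)
  truth <- -0.1 / 240
  est <- replicate(400, {
    t_ref <- c(0, 60, 120, 240)
    y <- 1 * (1 + truth * t_ref) + rnorm(4, 0, 0.05)
    s <- data.frame(peak_id = "p", tau = 0.32, intensity = y, error = 0.05,
                    start_time = t_ref, is_reference = TRUE)
    fit_drift(s)$relative_slope
  })
  expect_lt(abs(mean(est) - truth), 2 * sd(est) / sqrt(length(est)))
})

test_that("correcting an injected multiplicative drift restores the series exactly", {
  slope <- -0.00125
  s_clean <- make_series(84, A = 2, delays = delay_schedule("nine_delay")$delays,
                         start_times = delay_schedule("nine_delay")$start_times)
  s_drift <- s_clean
  fac <- 1 + slope * (s_drift$start_time - s_drift$start_time[1])
  s_drift$intensity <- s_drift$intensity * fac

  d <- fit_drift(s_drift)
  corr <- correct_deterioration(s_drift, d)
  # post-correction reference slope vanishes
  expect_lt(abs(fit_drift(corr)$slope), 1e-12)
  # and the original series is recovered point by point
  expect_equal(corr$intensity, s_clean$intensity, tolerance = 1e-9)
  # the generating selT1 comes back exactly
  fit <- fit_recovery(corr)
  expect_equal(fit$estimate[["selT1"]], 84, tolerance = 1e-6)
  # correction preserves the sign of inverted early points
  expect_equal(sign(corr$intensity), sign(s_drift$intensity))
  # zero slope is the identity
  s0 <- correct_deterioration(s_clean, drift_model(0))
  expect_equal(s0$intensity, s_clean$intensity)
  expect_error(correct_deterioration(s_drift, drift_model(-0.01)), "positive")
})

test_that("the recovery fit is exact on noiseless data", {
  s <- make_series(100, A = 1, D = -2)
  fit <- fit_recovery(s)
  expect_equal(fit$estimate[["selT1"]], 100, tolerance = 1e-6)
  expect_equal(fit$estimate[["A"]], 1, tolerance = 1e-6)
  expect_equal(fit$estimate[["D"]], -2, tolerance = 1e-6)
  expect_equal(fit$status, "ok")
  # the in vitro T4/T22 value round-trips the same way
  s253 <- make_series(253, A = 2, D = -4)
  expect_equal(fit_recovery(s253)$estimate[["selT1"]], 253, tolerance = 1e-6)
  expect_error(fit_recovery(make_series(84)[1:3, ]), "4 points")
})

test_that("the weighted optimum agrees with a brute-force grid oracle", {
  set.seed(7)
  s <- make_series(120, A = 1, D = -2, delays = c(30, 90, 300, 900),
                   noise_sd = 0.05)
  fit <- fit_recovery(s)
  oracle <- oracle_grid_fit(s, seq(10, 500, by = 0.25))
  expect_lt(abs(fit$estimate[["selT1"]] - oracle[["T1"]]) / oracle[["T1"]],
            0.005)
})

test_that("Monte-Carlo recovery at SNR 10 is calibrated", {
  # mean estimate within 2 SE of truth; 1-SE interval coverage near nominal
  set.seed(202)
  truth <- 84
  reps <- 400
  est <- matrix(NA_real_, reps, 2)
  for (i in seq_len(reps)) {
    s <- make_series(truth, A = 1, D = -2, noise_sd = 0.05)
    f <- fit_recovery(s)
    est[i, ] <- c(f$estimate[["selT1"]], f$se[["selT1"]])
  }
  expect_lt(abs(mean(est[, 1]) - truth), 2 * sd(est[, 1]) / sqrt(reps))
  covered <- mean((abs(est[, 1] - truth) <= est[, 2])[is.finite(est[, 2])])
  expect_gte(covered, 0.55)
  expect_lte(covered, 0.80)
})

test_that("unidentifiable series are flagged as failed, never silent", {
  set.seed(3)
  flat <- data.frame(peak_id = "p", tau = c(10, 50, 200, 800, 1500),
                     intensity = 1 + rnorm(5, 0, 0.02), error = 0.02,
                     start_time = 1:5, is_reference = FALSE)
  f <- fit_recovery(flat)
  expect_equal(f$status, "failed")
})

test_that("global fits share selT1 and reduce to the individual fit", {
  set.seed(9)
  s1 <- make_series(84, A = 1, D = -2, noise_sd = 0.05)
  ind <- fit_recovery(s1)
  glo <- fit_recovery_global(list(s1))
  expect_lt(abs(glo$estimate[["selT1"]] - ind$estimate[["selT1"]]) /
              ind$estimate[["selT1"]], 1e-8)

  # three noiseless series, common selT1, different amplitudes: exact
  sl <- lapply(1:3, function(a) make_series(84, A = a, D = -2 * a))
  g <- fit_recovery_global(sl)
  expect_equal(g$estimate[["selT1"]], 84, tolerance = 1e-6)
  expect_equal(g$per_series$A, 1:3, tolerance = 1e-6)
  expect_equal(g$per_series$D, -2 * (1:3), tolerance = 1e-6)
  expect_true(g$shared)
})

test_that("pooling replicates never hurts the shared-parameter precision", {
  set.seed(33)
  wins <- replicate(100, {
    sl <- lapply(1:3, function(i) make_series(84, A = 1, D = -2, noise_sd = 0.05))
    g <- fit_recovery_global(sl)
    ses <- vapply(sl, function(s) fit_recovery(s)$se[["selT1"]], numeric(1))
    g$se[["selT1"]] <= min(ses) + 1e-9
  })
  expect_gte(mean(wins, na.rm = TRUE), 0.95)
})

test_that("the shared optimum minimises the pooled weighted residuals", {
  set.seed(12)
  sl <- lapply(1:3, function(i) make_series(84, A = i, D = -2 * i, noise_sd = 0.05))
  g <- fit_recovery_global(sl)
  wrss_at <- function(T1) {
    sum(vapply(sl, function(s) {
      X <- cbind(1, exp(-s$tau / T1)) / s$error
      yw <- s$intensity / s$error
      sum((yw - X %*% qr.solve(X, yw))^2)
    }, numeric(1)))
  }
  opt <- wrss_at(g$estimate[["selT1"]])
  for (T1 in c(40, 70, 100, 150, 253))
    expect_gte(wrss_at(T1), opt - 1e-9)
})

test_that("normalisation divides by the fitted equilibrium amplitude", {
  s <- make_series(100, A = 2, D = -4, delays = c(1, 50, 100, 250, 500, 1000))
  f <- normalize_recovery(fit_recovery(s))
  expect_equal(f$normalized_points$normalized,
               s$intensity / 2, tolerance = 1e-6)
  # tau = 5 selT1 with perfect inversion: 1 - 2 exp(-5)
  s5 <- make_series(100, A = 2, D = -4, delays = c(1, 100, 250, 500))
  v5 <- (2 - 4 * exp(-500 / 100)) / 2
  expect_equal(v5, 1 - 2 * exp(-5))
  f5 <- normalize_recovery(fit_recovery(s5))
  expect_equal(f5$normalized_points$normalized[4], 1 - 2 * exp(-5),
               tolerance = 1e-6)
  # tau -> 0 limit under perfect inversion is -1
  expect_equal((2 - 4 * exp(-1e-9 / 100)) / 2, -1, tolerance = 1e-6)
})

test_that("replicates are renormalised via the re-measured reference delay", {
  s1 <- make_series(84, A = 1, D = -2)
  s2 <- make_series(84, A = 0.8, D = -1.6)  # 20% signal loss
  out <- renormalize_series(list(s1, s2))
  expect_equal(out[[2]]$intensity, s1$intensity, tolerance = 1e-12)
  expect_equal(out[[1]]$intensity, s1$intensity)
})

test_that("in vitro / in-cell ratio tables propagate uncertainties", {
  rt <- ratio_table(preset_selt1_table("in_vitro"),
                    preset_selt1_table("in_cell"), map = dsa2_peak_map())
  get <- function(v) rt[rt$peak_vitro == v, ]
  expect_equal(get("G11")$ratio_rounded, 4.5)
  expect_equal(get("T8")$ratio_rounded, 6.8)
  expect_equal(get("G20")$ratio_rounded, 2.9)
  expect_equal(get("G6")$ratio_rounded, 2.8)
  expect_equal(get("G11")$ratio_se,
               4.5 * sqrt((2 / 108)^2 + (2 / 24)^2), tolerance = 1e-9)
  # equal inputs give unit ratio; missing counterparts warn and skip
  tab <- data.frame(peak_id = "X", selT1 = 100, se = 5)
  expect_equal(ratio_table(tab, tab)$ratio, 1)
  expect_warning(out <- ratio_table(tab, data.frame(peak_id = "Y", selT1 = 1, se = 1),
                                    map = list(Y = "Z")), "in vitro")
  expect_equal(nrow(out), 0)
})
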