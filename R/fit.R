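#' Fit the sample-deterioration line through reference points
#'
#' Ordinary least squares of intensity against wall-clock start time using
#' only the repeated reference-delay points of a series. The line tracks
#' sample decay (cell death, degradation) over the measurement and is used
#' by [correct_deterioration()] as a multiplicative correction.
#'
#' @param series A `recovery_series` (one peak) with at least two reference
#'   points.
#' @return An object of class `drift_fit`: `intercept` (intensity at the
#'   first reference start time), `slope` (intensity/min) with `slope_se`,
#'   `relative_slope` (fraction/min), `t0`, and the underlying `lm`.
#' @export
fit_drift <- function(series) {
  refs <- series[series$is_reference, , drop = FALSE]
  if (nrow(refs) < 2)
    stop("need at least 2 reference points for the deterioration fit")
  t0 <- min(refs$start_time)
  m <- stats::lm(intensity ~ I(start_time - t0), data = refs)
  co <- stats::coef(m)
  se <- tryCatch(sqrt(diag(stats::vcov(m)))[2], error = function(e) NA_real_)
  structure(list(intercept = unname(co[1]), slope = unname(co[2]),
                 slope_se = unname(se),
                 relative_slope = unname(co[2] / co[1]),
                 t0 = t0, model = m),
            class = "drift_fit")
}

#' @export
print.drift_fit <- function(x, ...) {
  cat(sprintf("<drift_fit> %.3g %%/min (intercept %.4g at t0 = %.1f min)\n",
              100 * x$relative_slope, x$intercept, x$t0))
  invisible(x)
}

#' Correct a series for sample deterioration
#'
#' Divides every intensity and error by the drift factor, i.e. the fitted
#' reference line evaluated at the point's start time and normalised to 1
#' at the first reference time. The correction is multiplicative because
#' cell loss scales all signal proportionally; after correcting noiseless
#' drifted data the reference points are exactly flat. Positive factors
#' preserve the sign pattern of inverted early-delay points.
#'
#' @param series A `recovery_series`.
#' @param drift A `drift_fit` from [fit_drift()] (or a [drift_model()],
#'   whose known relative slope is then inverted exactly).
#' @return The corrected `recovery_series`.
#' @export
correct_deterioration <- function(series, drift) {
  rel <- if (inherits(drift, "drift_fit")) drift$relative_slope
         else if (inherits(drift, "drift_model")) drift$relative_slope
         else stop("'drift' must be a drift_fit or drift_model")
  t0 <- if (inherits(drift, "drift_fit")) drift$t0 else drift$reference_time
  fac <- 1 + rel * (series$start_time - t0)
  if (any(fac <= 0)) stop("drift factor must stay positive over the series")
  series$intensity <- series$intensity / fac
  series$error <- series$error / fac
  series
}

.recovery_init <- function(tau, y) {
  A0 <- y[which.max(tau)]
  D0 <- y[which.min(tau)] - A0
  if (D0 == 0) {
    T10 <- stats::median(tau)
  } else {
    T10 <- tau[which.min(abs(abs(y - A0) - abs(D0) / exp(1)))]
    if (T10 <= 0 || !is.finite(T10)) T10 <- stats::median(tau)
  }
  c(T1 = unname(T10), A = unname(A0), D = unname(D0))
}

.fit_status <- function(nlm_fit, est_T1, se_T1) {
  if (!(nlm_fit$info %in% 1:4)) return("failed")
  if (est_T1 <= 1e-6) return("failed")
  if (!is.finite(se_T1)) return("failed")       # singular covariance
  if (se_T1 / est_T1 > 1) return("failed")
  "ok"
}

#' Fit the mono-exponential inversion-recovery model
#'
#' Weighted nonlinear least squares of
#' \deqn{I(\tau) = A + D e^{-\tau/\mathrm{selT1}}}
#' over (`selT1`, `A`, `D`) by Levenberg-Marquardt, with weights
#' `1/error^2` when per-point errors are available (unit weights otherwise
#' or with `weighted = FALSE`). `selT1` is constrained positive. The
#' per-point errors are treated as absolute standard errors (the
#' extraction stage calibrates them as the spectrum RMS noise), so the
#' parameter covariance is `(J'WJ)^-1`; for unweighted fits it is scaled
#' by the reduced chi-square instead.
#'
#' Initialisation: `A0` is the intensity at the largest delay, `D0` the
#' intensity at the smallest delay minus `A0`, and `selT1_0` the delay at
#' which `|I - A0|` is nearest `|D0|/e` (falling back to the median delay).
#'
#' A fit is flagged `"failed"` (never silently) when the optimizer does not
#' converge, `selT1` collapses onto its bound, or the relative standard
#' error of `selT1` exceeds 100% -- the fate of peaks whose maxima wander
#' between experiments.
#'
#' @param series A `recovery_series` for one peak with at least 4
#'   non-reference points (3-parameter fit).
#' @param weighted Use `1/error^2` weights when errors are present.
#' @return An object of class `recovery_fit` with `estimate`
#'   (`selT1`, `A`, `D`), `se`, `covariance`, `status`, `data` and the
#'   number of iterations.
#' @export
fit_recovery <- function(series, weighted = TRUE) {
  tau <- series$tau
  y <- series$intensity
  if (length(tau) < 4) stop("need at least 4 points for a 3-parameter fit")
  if (any(tau <= 0)) stop("delays must be positive")
  err <- series$error
  use_w <- weighted && !is.null(err) && all(is.finite(err)) && all(err > 0)
  w <- if (use_w) 1 / err else rep(1, length(y))
  p0 <- .recovery_init(tau, y)
  fn <- function(p) (p[2] + p[3] * exp(-tau / p[1]) - y) * w
  # multi-start: a noisy series can drive the first start into the selT1
  # boundary; retry from schedule-scale starting values and keep the best
  starts <- list(p0,
                 c(stats::median(tau), p0[2], p0[3]),
                 c(max(tau) / 3, p0[2], p0[3]))
  fit <- NULL
  for (st in starts) {
    cand <- minpack.lm::nls.lm(par = st, fn = fn,
                               lower = c(1e-9, -Inf, -Inf),
                               control = minpack.lm::nls.lm.control(maxiter = 500))
    if (is.null(fit) || cand$deviance < fit$deviance) fit <- cand
    if (fit$info %in% 1:4 && fit$par[1] > 1e-6) break
  }
  est <- fit$par
  names(est) <- c("selT1", "A", "D")
  dof <- length(y) - 3L
  # with calibrated per-point errors the weights are absolute standard
  # errors and the covariance is (J'WJ)^-1; without them, scale by the
  # reduced chi-square as usual
  s2 <- if (use_w) 1 else if (dof > 0) fit$deviance / dof else 0
  cov <- tryCatch(solve(fit$hessian) * s2, error = function(e)
    matrix(NA_real_, 3, 3))
  dimnames(cov) <- list(names(est), names(est))
  se <- sqrt(pmax(diag(cov), 0))
  structure(list(estimate = est, se = se, covariance = cov,
                 status = .fit_status(fit, est[["selT1"]], se[["selT1"]]),
                 shared = FALSE, weighted = use_w,
                 peak_id = unique(series$peak_id),
                 data = series, niter = fit$niter, info = fit$info,
                 deviance = fit$deviance,
                 normalized_points = NULL),
            class = "recovery_fit")
}

#' Global recovery fit with a shared relaxation time
#'
#' Fits several series of the same peak (e.g. technical or biological
#' replicates, possibly measured with different delay schedules) jointly:
#' one shared `selT1`, one `A` and `D` per series. Pooling never increases
#' the weighted residual sum of squares relative to forcing each series to
#' the shared optimum, and with a single series the result coincides with
#' [fit_recovery()].
#'
#' @param series_list List of `recovery_series` (or a single series).
#' @param weighted Use `1/error^2` weights.
#' @return A `recovery_fit` with `shared = TRUE`; `per_series` holds the
#'   per-series amplitudes and their standard errors.
#' @export
fit_recovery_global <- function(series_list, weighted = TRUE) {
  if (inherits(series_list, "data.frame")) series_list <- list(series_list)
  m <- length(series_list)
  if (m < 1) stop("need at least one series")
  taus <- lapply(series_list, `[[`, "tau")
  ys <- lapply(series_list, `[[`, "intensity")
  have_err <- vapply(series_list, function(s)
    !is.null(s$error) && all(is.finite(s$error)) && all(s$error > 0),
    logical(1))
  use_w <- weighted && all(have_err)
  ws <- lapply(series_list, function(s) {
    if (use_w) 1 / s$error else rep(1, nrow(s))
  })
  inits <- mapply(function(tau, y) .recovery_init(tau, y), taus, ys)
  p0 <- c(stats::median(inits["T1", ]), as.vector(inits[c("A", "D"), ]))
  fn <- function(p) {
    T1 <- p[1]
    unlist(lapply(seq_len(m), function(i) {
      (p[2 * i] + p[2 * i + 1] * exp(-taus[[i]] / T1) - ys[[i]]) * ws[[i]]
    }))
  }
  fit <- minpack.lm::nls.lm(par = p0, fn = fn,
                            lower = c(1e-9, rep(-Inf, 2 * m)),
                            control = minpack.lm::nls.lm.control(maxiter = 1000))
  npar <- 1 + 2 * m
  n <- sum(lengths(ys))
  dof <- n - npar
  s2 <- if (use_w) 1 else if (dof > 0) fit$deviance / dof else 0
  cov <- tryCatch(solve(fit$hessian) * s2, error = function(e)
    matrix(NA_real_, npar, npar))
  se <- sqrt(pmax(diag(cov), 0))
  est <- c(selT1 = unname(fit$par[1]),
           A = unname(fit$par[2]), D = unname(fit$par[3]))
  per <- data.frame(series = seq_len(m),
                    A = fit$par[seq(2, 2 * m, by = 2)],
                    D = fit$par[seq(3, 2 * m + 1, by = 2)],
                    se_A = se[seq(2, 2 * m, by = 2)],
                    se_D = se[seq(3, 2 * m + 1, by = 2)])
  peak <- unique(unlist(lapply(series_list, function(s) unique(s$peak_id))))
  structure(list(estimate = est,
                 se = c(selT1 = unname(se[1]), A = unname(se[2]), D = unname(se[3])),
                 covariance = cov, per_series = per,
                 status = .fit_status(fit, fit$par[1], se[1]),
                 shared = TRUE, weighted = use_w,
                 peak_id = peak, data = series_list,
                 niter = fit$niter, info = fit$info,
                 deviance = fit$deviance,
                 normalized_points = NULL),
            class = "recovery_fit")
}

#' @export
print.recovery_fit <- function(x, ...) {
  cat(sprintf("<recovery_fit%s> %s: selT1 = %.4g +/- %.2g ms [%s]\n",
              if (x$shared) " (shared)" else "",
              paste(x$peak_id, collapse = ","),
              x$estimate[["selT1"]], x$se[["selT1"]], x$status))
  invisible(x)
}

#' Normalise a recovery fit by its equilibrium amplitude
#'
#' Divides the intensities (and errors) by the fitted equilibrium amplitude
#' `A`, the maximum peak intensity at infinite delay, so the normalised
#' curve tends to 1 as tau grows and starts near -1 for perfect inversion.
#' Global fits are normalised per series by their own `A`.
#'
#' @param fit A `recovery_fit` with nonzero fitted `A`.
#' @return The fit with `normalized_points` populated.
#' @export
normalize_recovery <- function(fit) {
  stopifnot(inherits(fit, "recovery_fit"))
  norm1 <- function(series, A) {
    if (A == 0) stop("cannot normalise: fitted A is zero")
    data.frame(tau = series$tau,
               normalized = series$intensity / A,
               error = series$error / abs(A),
               is_reference = series$is_reference,
               stringsAsFactors = FALSE)
  }
  if (fit$shared) {
    pts <- do.call(rbind, lapply(seq_along(fit$data), function(i) {
      d <- norm1(fit$data[[i]], fit$per_series$A[i])
      d$series <- i
      d
    }))
  } else {
    pts <- norm1(fit$data, fit$estimate[["A"]])
  }
  fit$normalized_points <- pts
  fit
}

#' Rescale replicate series onto a common intensity scale
#'
#' Technical replicates are renormalised via the re-measured reference
#' delay: every series is scaled by the ratio of the first series' first
#' reference intensity to its own, putting all replicates on the scale of
#' the first.
#'
#' @param series_list List of `recovery_series`, each with at least one
#'   reference point.
#' @return The rescaled list.
#' @export
renormalize_series <- function(series_list) {
  first_ref <- vapply(series_list, function(s) {
    refs <- s[s$is_reference, , drop = FALSE]
    if (nrow(refs) == 0) stop("every series needs a reference point")
    refs$intensity[which.min(refs$start_time)]
  }, numeric(1))
  lapply(seq_along(series_list), function(i) {
    s <- series_list[[i]]
    sc <- first_ref[1] / first_ref[i]
    s$intensity <- s$intensity * sc
    s$error <- s$error * abs(sc)
    s
  })
}

#' Ratio of in vitro to in-cell relaxation times
#'
#' Tabulates `selT1(in vitro) / selT1(in-cell)` per peak, with first-order
#' error propagation of the two standard errors. In-cell composite peaks
#' can be matched to several in vitro peaks via `map` (see
#' [dsa2_peak_map()]); ratios are computed from the unrounded values and
#' additionally reported rounded to one decimal.
#'
#' @param in_vitro,in_cell Data frames with columns `peak_id`, `selT1`,
#'   `se` (see [preset_selt1_table()]), or lists of `recovery_fit`s.
#' @param map Named list, in-cell peak id -> in vitro peak id(s). Default:
#'   identical ids.
#' @return Data frame with `peak_vitro`, `peak_cell`, `selT1_vitro`,
#'   `selT1_cell`, `ratio`, `ratio_se`, `ratio_rounded`.
#' @export
#' @examples
#' ratio_table(preset_selt1_table("in_vitro"), preset_selt1_table("in_cell"),
#'             map = dsa2_peak_map())
ratio_table <- function(in_vitro, in_cell, map = NULL) {
  as_table <- function(x) {
    if (is.data.frame(x)) return(x)
    data.frame(peak_id = vapply(x, function(f) paste(f$peak_id, collapse = ","),
                                character(1)),
               selT1 = vapply(x, function(f) f$estimate[["selT1"]], numeric(1)),
               se = vapply(x, function(f) f$se[["selT1"]], numeric(1)),
               stringsAsFactors = FALSE)
  }
  vit <- as_table(in_vitro)
  cel <- as_table(in_cell)
  if (is.null(map)) {
    ids <- intersect(cel$peak_id, vit$peak_id)
    map <- stats::setNames(as.list(ids), ids)
  }
  rows <- list()
  for (cid in names(map)) {
    if (!cid %in% cel$peak_id) { warning("no in-cell fit for ", cid); next }
    for (vid in map[[cid]]) {
      if (!vid %in% vit$peak_id) { warning("no in vitro fit for ", vid); next }
      tv <- vit$selT1[vit$peak_id == vid][1]
      sv <- vit$se[vit$peak_id == vid][1]
      tc <- cel$selT1[cel$peak_id == cid][1]
      sc <- cel$se[cel$peak_id == cid][1]
      r <- tv / tc
      rse <- r * sqrt((sv / tv)^2 + (sc / tc)^2)
      rows[[length(rows) + 1]] <- data.frame(
        peak_vitro = vid, peak_cell = cid,
        selT1_vitro = tv, selT1_cell = tc,
        ratio = r, ratio_se = rse, ratio_rounded = round(r, 1),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(peak_vitro = character(), peak_cell = character(),
                      selT1_vitro = numeric(), selT1_cell = numeric(),
                      ratio = numeric(), ratio_se = numeric(),
                      ratio_rounded = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
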