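# Baseline correction (asymmetric IRLS penalized least squares) and
# Savitzky-Golay smoothing of EICs.

#' Preprocessing parameters
#'
#' @param sg_window Savitzky-Golay window length in points; odd and at
#'   least `sg_order + 2`.
#' @param sg_order Savitzky-Golay polynomial order.
#' @param irls_lambda Roughness penalty of the baseline smoother. Larger
#'   values give stiffer baselines; the default 1e7 keeps the baseline from
#'   bulging into peaks on LC traces sampled at >= 1 Hz while still tracking
#'   linear and slow exponential drift.
#' @param irls_p Asymmetry weight in (0, 0.5): points above the current
#'   baseline fit get weight `irls_p`, points below get `1 - irls_p`, so the
#'   fit hugs the signal's lower envelope.
#' @param irls_tol Relative-change convergence tolerance for the baseline.
#' @param irls_max_iter Iteration cap for the reweighting loop.
#' @return An object of class `preprocess_params`.
#' @export
preprocess_params <- function(sg_window = 11L, sg_order = 3L,
                              irls_lambda = 1e7, irls_p = 0.001,
                              irls_tol = 1e-6, irls_max_iter = 50L) {
  sg_window <- as.integer(sg_window); sg_order <- as.integer(sg_order)
  if (sg_window %% 2L == 0L)
    stop_config("sg_window must be odd (got %d)", sg_window)
  if (sg_window < sg_order + 2L)
    stop_config("sg_window must be >= sg_order + 2 (got window %d, order %d)",
                sg_window, sg_order)
  if (irls_p <= 0 || irls_p >= 0.5)
    stop_config("irls_p must be in (0, 0.5)")
  if (irls_lambda <= 0) stop_config("irls_lambda must be positive")
  structure(list(sg_window = sg_window, sg_order = sg_order,
                 irls_lambda = irls_lambda, irls_p = irls_p,
                 irls_tol = irls_tol,
                 irls_max_iter = as.integer(irls_max_iter)),
            class = "preprocess_params")
}

params_from_config <- function(config) {
  pp <- config$preprocess
  preprocess_params(pp$sg_window, pp$sg_order, pp$irls_lambda, pp$irls_p,
                    pp$irls_tol, pp$irls_max_iter)
}

#' IRLS baseline estimation and subtraction
#'
#' Estimates a slowly varying baseline by iteratively reweighted penalized
#' least squares with asymmetric weights: at each iteration the baseline
#' minimizes `sum(w * (y - z)^2) + lambda * sum(diff(z, differences = 2)^2)`,
#' then weights are updated to `irls_p` where `y > z` (signal above the
#' baseline, e.g. peaks) and `1 - irls_p` where `y <= z`. Iteration stops
#' when the relative change in the baseline drops below `irls_tol` or after
#' `irls_max_iter` iterations.
#'
#' @param x An [eic()] with at least 5 points.
#' @param params A [preprocess_params()].
#' @return A list with `baseline` (numeric vector) and `corrected` (an
#'   [eic()] with intensity `pmax(raw - baseline, 0)`).
#' @export
irls_baseline <- function(x, params = preprocess_params()) {
  stopifnot(inherits(x, "eic"))
  y <- x$intensity
  if (any(!is.finite(y))) stop_validation("non-finite intensities in EIC")
  n <- length(y)
  D <- Matrix::bandSparse(n - 2L, n, k = 0:2,
                          diagonals = list(rep(1, n - 2L), rep(-2, n - 2L),
                                           rep(1, n - 2L)))
  DtD <- params$irls_lambda * Matrix::crossprod(D)
  w <- rep(1, n)
  z <- y
  scale <- max(abs(y), 1)
  for (iter in seq_len(params$irls_max_iter)) {
    W <- Matrix::Diagonal(x = w)
    z_new <- as.numeric(Matrix::solve(W + DtD, w * y))
    delta <- max(abs(z_new - z)) / scale
    z <- z_new
    if (iter > 1L && delta < params$irls_tol) break
    w <- ifelse(y > z, params$irls_p, 1 - params$irls_p)
  }
  corrected <- x
  corrected$intensity <- pmax(y - z, 0)
  list(baseline = z, corrected = corrected)
}

#' Savitzky-Golay smoothing
#'
#' Standard Savitzky-Golay polynomial smoothing. Edge points are handled by
#' the filter's startup/end transients, which re-fit the polynomial to the
#' truncated first and last half-windows — deterministic and
#' length-preserving.
#'
#' @param x An [eic()].
#' @param params A [preprocess_params()]; uses `sg_window` and `sg_order`.
#' @return The smoothed [eic()].
#' @export
savgol_smooth <- function(x, params = preprocess_params()) {
  stopifnot(inherits(x, "eic"))
  n <- length(x$intensity)
  if (params$sg_window > n)
    stop_config("sg_window (%d) exceeds EIC length (%d)", params$sg_window, n)
  x$intensity <- signal::sgolayfilt(x$intensity, p = params$sg_order,
                                    n = params$sg_window)
  x
}

#' Baseline-correct and smooth an EIC
#'
#' The fixed preprocessing pipeline: IRLS baseline subtraction first, then
#' Savitzky-Golay smoothing, then clipping at zero (the downstream metrics
#' assume a non-negative signal).
#'
#' @param x A raw [eic()].
#' @param params A [preprocess_params()].
#' @return An object of class `corrected_eic` with fields `eic` (the
#'   corrected, smoothed trace), `corrected_raw` (baseline-subtracted but
#'   unsmoothed intensities, used by the MCQ metric), `baseline`, and `raw`
#'   (the input EIC).
#' @export
correct_eic <- function(x, params = preprocess_params()) {
  bl <- irls_baseline(x, params)
  sm <- savgol_smooth(bl$corrected, params)
  sm$intensity <- pmax(sm$intensity, 0)
  structure(list(eic = sm, corrected_raw = bl$corrected$intensity,
                 baseline = bl$baseline, raw = x),
            class = "corrected_eic")
}

#' @export
print.corrected_eic <- function(x, ...) {
  cat(sprintf("<corrected_eic> %s: %d points, max corrected intensity %.4g\n",
              x$eic$analyte_id, length(x$eic$rt), max(x$eic$intensity)))
  invisible(x)
}
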