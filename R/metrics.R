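# The eight peak-quality metrics. Undefined metrics are NA_real_, never 0;
# every validation rule downstream treats NA as a failure (fail-closed).

#' Mass chromatographic quality (MCQ)
#'
#' CODA-style similarity between a chromatogram and its smoothed,
#' standardized form. Let `y` be the `window`-point moving average of the
#' trace (aligned to the interior of the raw trace), `yhat` its
#' standardization `(y - mean(y)) / sd(y)`, and `xhat` the corresponding raw
#' segment scaled to unit length. Then `MCQ = sum(xhat * yhat) / sqrt(m - 1)`
#' over the `m` aligned points, clipped to `[0, 1]`. Clean peaks score near
#' 1; noise-dominated traces score low. Scale-invariant by construction.
#'
#' @param x An [eic()] (baseline-corrected, unsmoothed) or a numeric vector.
#' @param window Moving-average window in points (odd; default 3,
#'   independent of the preprocessing smoother).
#' @return MCQ in `[0, 1]`; a constant trace is defined as 0.
#' @export
mcq <- function(x, window = 3L) {
  v <- if (inherits(x, "eic")) x$intensity else as.numeric(x)
  window <- as.integer(window)
  if (window %% 2L == 0L) stop_config("mcq window must be odd")
  n <- length(v)
  if (n < window + 2L)
    stop_validation("EIC too short for MCQ (need > window + 1 points)")
  h <- (window - 1L) %/% 2L
  m <- n - 2L * h
  # centered moving average over the interior, aligned raw segment
  cs <- cumsum(c(0, v))
  sm <- (cs[(1L + 2L * h + 1L):(n + 1L)] - cs[1L:m]) / window
  xa <- v[(h + 1L):(n - h)]
  s <- stats::sd(sm)
  nx <- sqrt(sum(xa^2))
  if (s == 0 || nx == 0) return(0)
  yhat <- (sm - mean(sm)) / s
  val <- sum((xa / nx) * yhat) / sqrt(m - 1)
  min(max(val, 0), 1)
}

# interpolated RT where the signal crosses `target` between the apex and
# one region edge; NA when it never crosses inside the region
cross_rt <- function(rt, y, apex, edge, target) {
  step <- if (edge < apex) -1L else 1L
  i <- apex
  while (i != edge) {
    nxt <- i + step
    if (y[nxt] <= target) {
      if (y[i] == y[nxt]) return(rt[nxt])
      f <- (y[i] - target) / (y[i] - y[nxt])
      return(rt[i] + f * (rt[nxt] - rt[i]))
    }
    i <- nxt
  }
  NA_real_
}

#' Asymmetry factor
#'
#' Ratio of the trailing to the leading half-width at `height_frac` of the
#' apex intensity (default 10%, the chromatographic asymmetry-factor
#' convention). Crossings are located by linear interpolation between
#' samples within the peak region: `As = (rt_right - rt_apex) /
#' (rt_apex - rt_left)`. 1 for a symmetric peak, > 1 for tailing.
#'
#' @param x A `corrected_eic` or [eic()].
#' @param peak A `peak_region` from [detect_peaks()].
#' @param height_frac Fraction of apex height at which to measure.
#' @return The asymmetry factor, or `NA` when a crossing falls outside the
#'   peak region.
#' @export
asymmetry_factor <- function(x, peak, height_frac = 0.10) {
  e <- if (inherits(x, "corrected_eic")) x$eic else x
  target <- height_frac * peak$apex_intensity
  lrt <- cross_rt(e$rt, e$intensity, peak$apex_idx, peak$left_idx, target)
  rrt <- cross_rt(e$rt, e$intensity, peak$apex_idx, peak$right_idx, target)
  if (is.na(lrt) || is.na(rrt)) return(NA_real_)
  apex_rt <- e$rt[peak$apex_idx]
  if (apex_rt - lrt <= 0) return(NA_real_)
  (rrt - apex_rt) / (apex_rt - lrt)
}

#' Full width at half maximum
#'
#' Width in minutes between the linearly interpolated crossings at half the
#' apex intensity.
#'
#' @inheritParams asymmetry_factor
#' @return FWHM in minutes, or `NA` when a crossing falls outside the region.
#' @export
fwhm <- function(x, peak) {
  e <- if (inherits(x, "corrected_eic")) x$eic else x
  target <- 0.5 * peak$apex_intensity
  lrt <- cross_rt(e$rt, e$intensity, peak$apex_idx, peak$left_idx, target)
  rrt <- cross_rt(e$rt, e$intensity, peak$apex_idx, peak$right_idx, target)
  if (is.na(lrt) || is.na(rrt)) return(NA_real_)
  rrt - lrt
}

#' Jaggedness
#'
#' Fraction of excess sign changes in the first differences of the peak
#' region, ignoring zero differences. An ideal unimodal peak has exactly one
#' sign change (rise to fall) and scores 0; an alternating sawtooth
#' approaches 1.
#'
#' @inheritParams asymmetry_factor
#' @return Jaggedness in `[0, 1]`.
#' @export
jaggedness <- function(x, peak) {
  e <- if (inherits(x, "corrected_eic")) x$eic else x
  y <- e$intensity[peak$left_idx:peak$right_idx]
  if (length(y) < 4L) return(NA_real_)
  d <- diff(y)
  s <- sign(d)
  s <- s[s != 0]
  changes <- if (length(s) > 1L) sum(s[-1L] != s[-length(s)]) else 0L
  max(0, changes - 1L) / (length(d) - 1L)
}

#' Modality
#'
#' Depth of the largest interior dip of the peak region relative to the apex
#' intensity. For every interior local minimum, the dip is the height of the
#' lower of its two flanking local maxima minus the minimum's intensity;
#' modality is the largest dip divided by the apex intensity, and 0 when the
#' region has no interior local minimum (unimodal).
#'
#' @inheritParams asymmetry_factor
#' @return Modality in `[0, 1]`.
#' @export
modality <- function(x, peak) {
  e <- if (inherits(x, "corrected_eic")) x$eic else x
  y <- e$intensity[peak$left_idx:peak$right_idx]
  n <- length(y)
  if (n < 3L) return(0)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n], FALSE)
  is_min <- c(FALSE, y[2:(n - 1)] < y[1:(n - 2)] & y[2:(n - 1)] <= y[3:n], FALSE)
  maxima <- which(is_max)
  minima <- which(is_min)
  if (length(minima) == 0L || length(maxima) < 2L) return(0)
  dip <- 0
  for (m in minima) {
    left_max <- maxima[maxima < m]
    right_max <- maxima[maxima > m]
    if (length(left_max) == 0L || length(right_max) == 0L) next
    flank <- min(y[max(left_max)], y[min(right_max)])
    dip <- max(dip, flank - y[m])
  }
  dip / peak$apex_intensity
}

#' Retention-time relative standard deviation across replicates
#'
#' @param rts Apex retention times (minutes) of the same analyte in
#'   replicate injections.
#' @return `100 * sd(rts) / mean(rts)` (percent), or `NA` with fewer than 2
#'   values.
#' @export
rsd_rt <- function(rts) {
  rts <- rts[!is.na(rts)]
  if (length(rts) < 2L) return(NA_real_)
  m <- mean(rts)
  if (m <= 0) return(NA_real_)
  100 * stats::sd(rts) / m
}

#' Standard-over-blank intensity ratio
#'
#' Ratio of the sample's apex intensity to the blank channel's local maximum
#' within `rt_halfwindow` minutes of the apex (co-eluting blank signal is
#' what confounds identification, so the local — not global — blank maximum
#' is used). The blank maximum is floored at `epsilon` counts, so a silent
#' blank yields a large but finite ratio.
#'
#' @param sample_intensity Apex intensity of the sample peak.
#' @param blank An [eic()] of the same analyte from the blank run, or `NULL`.
#' @param rt_apex Apex retention time (minutes).
#' @param rt_halfwindow Half-window in minutes (default 0.5).
#' @param epsilon Floor for the blank intensity (default 1 count).
#' @return The ratio, or `NA` when no blank is available.
#' @export
std_blk <- function(sample_intensity, blank, rt_apex, rt_halfwindow = 0.5,
                    epsilon = 1) {
  if (is.null(blank)) return(NA_real_)
  e <- if (inherits(blank, "corrected_eic")) blank$eic else blank
  inwin <- e$rt >= rt_apex - rt_halfwindow & e$rt <= rt_apex + rt_halfwindow
  b <- if (any(inwin)) max(e$intensity[inwin]) else 0
  sample_intensity / max(b, epsilon)
}

#' Assemble the eight peak-quality metrics for one analyte peak
#'
#' Computes MCQ on the baseline-corrected unsmoothed trace, the morphology
#' metrics (jaggedness, asymmetry factor, FWHM, modality) and the maximum
#' intensity on the corrected smoothed trace, the retention-time RSD from
#' the supplied replicate apex RTs, and Std/Blk against the blank channel.
#' Metrics whose inputs are absent (no blank, a single replicate) are `NA`,
#' never silently zero.
#'
#' @param corrected A `corrected_eic` from [correct_eic()].
#' @param peak The selected `peak_region`.
#' @param blank Blank-channel [eic()] or `corrected_eic`, or `NULL`.
#' @param replicate_rts Apex RTs of this analyte across replicates, or `NULL`.
#' @param config Configuration list (section `metrics`).
#' @return An object of class `peak_metrics`: named list with fields `mcq`,
#'   `max_intensity`, `rsd_rt`, `std_blk`, `jaggedness`, `asymmetry`,
#'   `fwhm`, `modality`.
#' @export
evaluate_peak <- function(corrected, peak, blank = NULL,
                          replicate_rts = NULL, config = default_config()) {
  stopifnot(inherits(corrected, "corrected_eic"), inherits(peak, "peak_region"))
  mc <- config$metrics
  structure(list(
    mcq = mcq(corrected$corrected_raw, window = mc$mcq_window),
    max_intensity = peak$apex_intensity,
    rsd_rt = if (is.null(replicate_rts)) NA_real_ else rsd_rt(replicate_rts),
    std_blk = std_blk(peak$apex_intensity, blank, peak$rt_apex,
                      rt_halfwindow = mc$blank_rt_halfwindow,
                      epsilon = mc$blank_epsilon),
    jaggedness = jaggedness(corrected, peak),
    asymmetry = asymmetry_factor(corrected, peak,
                                 height_frac = mc$asymmetry_height_frac),
    fwhm = fwhm(corrected, peak),
    modality = modality(corrected, peak)
  ), class = "peak_metrics")
}

metric_names <- c("mcq", "max_intensity", "rsd_rt", "std_blk",
                  "jaggedness", "asymmetry", "fwhm", "modality")

#' @export
print.peak_metrics <- function(x, ...) {
  cat("<peak_metrics>\n")
  for (nm in metric_names)
    cat(sprintf("  %-13s %s\n", nm,
                if (is.na(x[[nm]])) "NA" else format(x[[nm]], digits = 5)))
  invisible(x)
}
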