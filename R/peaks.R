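# Peak detection in corrected EICs and analyte-peak selection.

#' Detect candidate peaks in a corrected EIC
#'
#' Apexes are strict local maxima (plateaus of equal values count once, at
#' their first point) whose intensity is at least `min_rel_height` times the
#' global maximum. Peak boundaries extend outward from the apex to the
#' nearest local minimum, or to the first point where the intensity falls to
#' `boundary_frac` times the apex intensity, whichever comes first. Regions
#' spanning fewer than `min_points` samples are discarded. Detection is
#' deliberately permissive: quality filtering happens later via the metric
#' thresholds.
#'
#' @param x A `corrected_eic` (or an [eic()] that is already corrected and
#'   smoothed).
#' @param min_rel_height Minimum apex height as a fraction of the global max.
#' @param boundary_frac Boundary cutoff as a fraction of the apex intensity.
#' @param min_points Minimum number of samples in a region.
#' @return A list of `peak_region` objects (fields `apex_idx`, `left_idx`,
#'   `right_idx`, `rt_apex`, `apex_intensity`), sorted by `rt_apex`. An
#'   all-zero EIC yields an empty list.
#' @export
detect_peaks <- function(x, min_rel_height = 0.01, boundary_frac = 0.01,
                         min_points = 5L) {
  e <- if (inherits(x, "corrected_eic")) x$eic else x
  stopifnot(inherits(e, "eic"))
  y <- e$intensity
  n <- length(y)
  gmax <- max(y)
  if (gmax <= 0) return(list())
  out <- list()
  i <- 2L
  while (i < n) {
    if (y[i] > y[i - 1L]) {
      # ride out any plateau of equal values
      j <- i
      while (j < n && y[j + 1L] == y[j]) j <- j + 1L
      if (j < n && y[j + 1L] < y[j] && y[i] >= min_rel_height * gmax) {
        apex <- i
        cutoff <- boundary_frac * y[apex]
        left <- apex
        while (left > 1L && y[left] > cutoff && y[left - 1L] <= y[left])
          left <- left - 1L
        right <- j
        while (right < n && y[right] > cutoff && y[right + 1L] <= y[right])
          right <- right + 1L
        if (right - left + 1L >= min_points && left < apex && right > apex) {
          out[[length(out) + 1L]] <- structure(
            list(apex_idx = apex, left_idx = left, right_idx = right,
                 rt_apex = e$rt[apex], apex_intensity = y[apex]),
            class = "peak_region")
        }
        i <- j + 1L
      } else {
        i <- j + 1L
      }
    } else {
      i <- i + 1L
    }
  }
  out[order(vapply(out, `[[`, numeric(1), "rt_apex"))]
}

#' Select the analyte peak among detected candidates
#'
#' When the analyte has an expected RT window, candidates outside it are
#' dropped; among the remainder the peak with the highest apex intensity is
#' returned (ties broken by earliest apex RT). One peak per analyte is
#' reported because the reference library records a single retention time
#' per metabolite.
#'
#' @param peaks A list of `peak_region`s from [detect_peaks()].
#' @param spec The [analyte_spec()] the peaks belong to.
#' @return A single `peak_region`, or `NULL` when no candidate qualifies.
#' @export
select_analyte_peak <- function(peaks, spec) {
  if (length(peaks) == 0L) return(NULL)
  if (!is.null(spec$rt_window)) {
    rts <- vapply(peaks, `[[`, numeric(1), "rt_apex")
    peaks <- peaks[rts >= spec$rt_window[1] & rts <= spec$rt_window[2]]
    if (length(peaks) == 0L) return(NULL)
  }
  ints <- vapply(peaks, `[[`, numeric(1), "apex_intensity")
  rts <- vapply(peaks, `[[`, numeric(1), "rt_apex")
  best <- order(-ints, rts)[1L]
  peaks[[best]]
}
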