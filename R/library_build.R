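# Retention-time reference library: replicate standard injections plus a
# blank in, validated per-analyte entries out.

#' Library validation thresholds
#'
#' @param r Minimum standard-over-blank ratio (default 6, chosen to curb
#'   false-positive detections near background).
#' @param c Maximum retention-time RSD across replicates, percent
#'   (default 15).
#' @param I Minimum mean peak intensity in counts (default 1000).
#' @return An object of class `validation_thresholds`.
#' @export
validation_thresholds <- function(r = 6, c = 15, I = 1000) {
  if (!is.numeric(r) || r <= 0) stop_config("threshold r must be > 0")
  if (!is.numeric(c) || c <= 0 || c > 100)
    stop_config("threshold c must be in (0, 100]")
  if (!is.numeric(I) || I <= 0) stop_config("threshold I must be > 0")
  structure(list(r = r, c = c, I = I), class = "validation_thresholds")
}

#' Apply the r/c/I validation rules to one aggregated entry
#'
#' Comparisons are inclusive: an entry passes with `std_blk >= r`,
#' `rsd_rt <= c` and `max_intensity >= I`. Undefined (`NA`) metrics fail
#' the corresponding rule (fail-closed), and an analyte that lacks a peak
#' in any replicate fails outright.
#'
#' @param metrics A `peak_metrics` record (aggregated across replicates).
#' @param thresholds A [validation_thresholds()].
#' @param peak_in_all Logical: was a peak found in every replicate?
#' @return Character vector of violated rule names (empty when validated):
#'   a subset of `"std_blk_below_r"`, `"rsd_above_c"`, `"intensity_below_I"`,
#'   `"missing_replicate_peak"`.
#' @export
validate_entry <- function(metrics, thresholds = validation_thresholds(),
                           peak_in_all = TRUE) {
  reasons <- character(0)
  if (!isTRUE(peak_in_all)) reasons <- c(reasons, "missing_replicate_peak")
  if (is.na(metrics$std_blk) || metrics$std_blk < thresholds$r)
    reasons <- c(reasons, "std_blk_below_r")
  if (is.na(metrics$rsd_rt) || metrics$rsd_rt > thresholds$c)
    reasons <- c(reasons, "rsd_above_c")
  if (is.na(metrics$max_intensity) || metrics$max_intensity < thresholds$I)
    reasons <- c(reasons, "intensity_below_I")
  reasons
}

# Run the full per-analyte pipeline over replicate runs (and optional
# blank): extract -> correct -> detect -> select -> per-replicate metrics ->
# aggregate. Shared by build_library() and the phase-comparison front end.
# Aggregation: arithmetic mean for intensity, Std/Blk and the morphology
# metrics (NA propagates, fail-closed); rsd_rt from the per-replicate apex
# RTs. Returns a named list per analyte with fields `metrics` (aggregated
# peak_metrics), `rts`, `n_found`, `n_replicates`, `rt_mean`.
evaluate_analytes <- function(replicate_runs, blank_run = NULL, analytes,
                              config = default_config()) {
  pp <- params_from_config(config)
  pk <- config$peaks
  out <- list()
  for (spec in analytes) {
    blank_ce <- NULL
    if (!is.null(blank_run)) {
      blank_eic <- extract_eic(blank_run, spec, is_blank = TRUE)
      blank_ce <- correct_eic(blank_eic, pp)
    }
    per_rep <- lapply(seq_along(replicate_runs), function(i) {
      x <- extract_eic(replicate_runs[[i]], spec, replicate = i)
      ce <- correct_eic(x, pp)
      regions <- detect_peaks(ce, min_rel_height = pk$min_rel_height,
                              boundary_frac = pk$boundary_frac,
                              min_points = pk$min_points)
      sel <- select_analyte_peak(regions, spec)
      if (is.null(sel)) return(NULL)
      list(metrics = evaluate_peak(ce, sel, blank = blank_ce, config = config),
           rt = sel$rt_apex)
    })
    found <- !vapply(per_rep, is.null, logical(1))
    rts <- vapply(per_rep[found], `[[`, numeric(1), "rt")
    agg <- setNames(rep(NA_real_, length(metric_names)), metric_names)
    if (any(found)) {
      for (nm in setdiff(metric_names, "rsd_rt")) {
        vals <- vapply(per_rep[found], function(r) r$metrics[[nm]], numeric(1))
        agg[[nm]] <- mean(vals)        # NA in any replicate propagates
      }
    }
    agg[["rsd_rt"]] <- rsd_rt(rts)
    out[[spec$analyte_id]] <- list(
      metrics = structure(as.list(agg), class = "peak_metrics"),
      rts = rts, n_found = sum(found),
      n_replicates = length(replicate_runs),
      rt_mean = if (all(found)) mean(rts) else NA_real_)
  }
  out
}

#' Build a validated retention-time reference library
#'
#' Runs each analyte of a standard mixture through the full pipeline in
#' every replicate injection (extraction, baseline correction and smoothing,
#' peak detection, metric computation against the blank channel), aggregates
#' across replicates, and applies the r/c/I validation rules. An analyte is
#' validated when its mean Std/Blk is at least `r`, its retention-time RSD
#' at most `c` percent, its mean apex intensity at least `I`, and a peak was
#' found in every replicate; `fail_reasons` enumerates every violated rule.
#'
#' @param replicate_runs List of at least 2 (typically 3) `ms_run`s of the
#'   same standard mixture.
#' @param blank_run An `ms_run` of the blank injection, or `NULL` (then
#'   Std/Blk is undefined and the `r` rule fails closed).
#' @param analytes List of [analyte_spec()]s.
#' @param thresholds A [validation_thresholds()].
#' @param config Configuration list.
#' @return An object of class `analyte_library`: a list of `library_entry`
#'   records with fields `analyte_id`, `rt_mean` (mean apex RT, defined only
#'   when a peak was found in every replicate), `metrics`, `validated`,
#'   `fail_reasons`.
#' @export
build_library <- function(replicate_runs, blank_run = NULL, analytes,
                          thresholds = validation_thresholds(),
                          config = default_config()) {
  if (length(replicate_runs) < 2L)
    stop_config("build_library needs at least 2 replicate runs (got %d)",
                length(replicate_runs))
  evals <- evaluate_analytes(replicate_runs, blank_run, analytes, config)
  entries <- lapply(names(evals), function(id) {
    ev <- evals[[id]]
    reasons <- validate_entry(ev$metrics, thresholds,
                              peak_in_all = ev$n_found == ev$n_replicates)
    structure(list(analyte_id = id, rt_mean = ev$rt_mean,
                   metrics = ev$metrics,
                   validated = length(reasons) == 0L,
                   fail_reasons = reasons),
              class = "library_entry")
  })
  structure(entries, class = "analyte_library")
}

#' @export
print.analyte_library <- function(x, ...) {
  nval <- sum(vapply(x, `[[`, logical(1), "validated"))
  cat(sprintf("<analyte_library> %d entries, %d validated\n", length(x), nval))
  invisible(x)
}

#' Convert a library to a data frame
#'
#' @param x An `analyte_library`.
#' @param ... Unused.
#' @return A data frame with the documented column order: `analyte_id`,
#'   `rt_mean`, the eight metrics, `validated`, `fail_reasons`
#'   (semicolon-joined).
#' @export
as.data.frame.analyte_library <- function(x, ...) {
  rows <- lapply(x, function(e) {
    m <- e$metrics
    data.frame(analyte_id = e$analyte_id, rt_mean = e$rt_mean,
               mcq = m$mcq, max_intensity = m$max_intensity,
               rsd_rt = m$rsd_rt, std_blk = m$std_blk,
               jaggedness = m$jaggedness, asymmetry = m$asymmetry,
               fwhm = m$fwhm, modality = m$modality,
               validated = e$validated,
               fail_reasons = paste(e$fail_reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a reference library to CSV
#'
#' Undefined metrics are serialized as `NA`, never as 0; `fail_reasons` are
#' semicolon-joined. The file round-trips losslessly through
#' [read_library()].
#'
#' @param x An `analyte_library` (or its data frame form).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_library <- function(x, path) {
  df <- if (inherits(x, "analyte_library")) as.data.frame(x) else x
  write_table(df, path)
}

#' Read a reference library CSV written by [write_library()]
#'
#' @param path CSV path.
#' @return A data frame in the library column order.
#' @export
read_library <- function(path) {
  if (!file.exists(path)) stop_parse("library file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("analyte_id", "rt_mean", metric_names, "validated", "fail_reasons")
  if (!all(needed %in% names(df)))
    stop_config("library CSV %s is missing column(s): %s", path,
                paste(setdiff(needed, names(df)), collapse = ", "))
  df$fail_reasons[is.na(df$fail_reasons)] <- ""
  df
}
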