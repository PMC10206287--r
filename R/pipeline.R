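# High-level front ends tying io -> preprocess -> peaks -> metrics together.

#' Compare mobile phases from replicate runs
#'
#' Runs the full evaluation pipeline for every phase (each represented by
#' one or more replicate runs of the same standard mixture), validates
#' analytes by the `phase$intensity_min` / `phase$mcq_min` thresholds, and
#' scores the phases with [score_phases()].
#'
#' @param phase_runs Named list mapping phase_id to a list of `ms_run`s.
#' @param analytes List of [analyte_spec()]s.
#' @param blank_run Optional shared blank `ms_run` (only used for the
#'   Std/Blk metric column; phase validation itself uses intensity and MCQ).
#' @param config Configuration list.
#' @return A list with `scores` (a `phase_score_table`), `phases` (the
#'   `phase_result`s) and `metrics` (per-phase metric data frames).
#' @export
compare_phases <- function(phase_runs, analytes, blank_run = NULL,
                           config = default_config()) {
  if (length(phase_runs) < 2L)
    stop_config("need at least 2 phases (got %d)", length(phase_runs))
  if (is.null(names(phase_runs)) || any(!nzchar(names(phase_runs))))
    stop_config("phase_runs must be a named list (phase_id = runs)")
  phases <- lapply(names(phase_runs), function(pid) {
    runs <- phase_runs[[pid]]
    if (inherits(runs, "ms_run")) runs <- list(runs)
    evals <- evaluate_analytes(runs, blank_run, analytes, config)
    found <- vapply(evals, function(e) e$n_found > 0L, logical(1))
    per_analyte <- lapply(evals[found], `[[`, "metrics")
    phase_result(pid, per_analyte,
                 intensity_min = config$phase$intensity_min,
                 mcq_min = config$phase$mcq_min)
  })
  scores <- score_phases(phases, alpha = config$phase$alpha,
                         saf_criterion = config$phase$saf_criterion)
  metrics <- lapply(phases, function(p) metrics_table(p$per_analyte))
  names(metrics) <- vapply(phases, `[[`, character(1), "phase_id")
  list(scores = scores, phases = phases, metrics = metrics)
}

#' Tabulate per-analyte metrics
#'
#' @param per_analyte Named list of `peak_metrics`.
#' @return A data frame with one row per analyte and the eight metric
#'   columns in their documented order.
#' @export
metrics_table <- function(per_analyte) {
  rows <- lapply(names(per_analyte), function(id) {
    m <- per_analyte[[id]]
    cbind(data.frame(analyte_id = id, stringsAsFactors = FALSE),
          as.data.frame(setNames(lapply(metric_names, function(nm)
            as.numeric(m[[nm]])), metric_names)))
  })
  if (length(rows) == 0L)
    return(as.data.frame(setNames(
      c(list(character(0)), lapply(metric_names, function(x) numeric(0))),
      c("analyte_id", metric_names))))
  do.call(rbind, rows)
}

#' Compute the eight metrics for a single EIC
#'
#' The metrics-only path (e.g. for exporting metric tables as ML features):
#' preprocesses one EIC, detects and selects the analyte peak, and returns
#' its metric record.
#'
#' @param x A raw [eic()].
#' @param blank Optional blank [eic()].
#' @param spec Optional [analyte_spec()] (for the RT window); defaults to an
#'   unconstrained spec.
#' @param config Configuration list.
#' @return A `peak_metrics`, or `NULL` when no peak is detected.
#' @export
evaluate_eic <- function(x, blank = NULL, spec = NULL,
                         config = default_config()) {
  stopifnot(inherits(x, "eic"))
  pp <- params_from_config(config)
  pk <- config$peaks
  ce <- correct_eic(x, pp)
  regions <- detect_peaks(ce, min_rel_height = pk$min_rel_height,
                          boundary_frac = pk$boundary_frac,
                          min_points = pk$min_points)
  if (is.null(spec))
    spec <- analyte_spec(x$analyte_id, target_mz = 100)
  sel <- select_analyte_peak(regions, spec)
  if (is.null(sel)) return(NULL)
  blank_ce <- if (!is.null(blank)) correct_eic(blank, pp) else NULL
  evaluate_peak(ce, sel, blank = blank_ce, config = config)
}
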