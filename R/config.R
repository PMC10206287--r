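#' Default chromeval configuration
#'
#' Returns the full nested configuration with the shipped defaults. The
#' validation thresholds follow common practice for quality-control
#' filtering of standard mixtures: `thresholds$r = 6` (minimum
#' standard-over-blank ratio), `thresholds$c = 15` (maximum retention-time
#' RSD across replicates, percent) and `thresholds$I = 1000` (minimum peak
#' intensity, counts).
#'
#' @return A nested named list with sections `io`, `preprocess`, `peaks`,
#'   `metrics`, `phase` and `thresholds`.
#'
#' @details Sections and keys:
#' \describe{
#'   \item{io}{`mz_tol` (default 10), `mz_tol_unit` ("ppm" or "Th").}
#'   \item{preprocess}{`sg_window` (points, odd), `sg_order`,
#'     `irls_lambda`, `irls_p`, `irls_tol`, `irls_max_iter`.}
#'   \item{peaks}{`min_rel_height`, `boundary_frac`, `min_points`.}
#'   \item{metrics}{`asymmetry_height_frac`, `mcq_window`,
#'     `blank_rt_halfwindow` (minutes), `blank_epsilon` (counts).}
#'   \item{phase}{`alpha`, `intensity_min`, `mcq_min`, `saf_criterion`
#'     ("distance_to_one" or "lowest_mean").}
#'   \item{thresholds}{`r`, `c`, `I` for library validation.}
#' }
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$thresholds$r
default_config <- function() {
  list(
    io = list(
      mz_tol = 10,
      mz_tol_unit = "ppm"
    ),
    preprocess = list(
      sg_window = 11L,
      sg_order = 3L,
      irls_lambda = 1e7,
      irls_p = 0.001,
      irls_tol = 1e-6,
      irls_max_iter = 50L
    ),
    peaks = list(
      min_rel_height = 0.01,
      boundary_frac = 0.01,
      min_points = 5L
    ),
    metrics = list(
      asymmetry_height_frac = 0.10,
      mcq_window = 3L,
      blank_rt_halfwindow = 0.5,
      blank_epsilon = 1
    ),
    phase = list(
      alpha = 0.05,
      intensity_min = 1000,
      mcq_min = 0.5,
      saf_criterion = "distance_to_one"
    ),
    thresholds = list(
      r = 6,
      c = 15,
      I = 1000
    )
  )
}

#' Load a configuration file and merge it onto the defaults
#'
#' Reads a YAML configuration file (a strict subset of the keys returned by
#' [default_config()]) and merges it onto the defaults. Unknown keys are
#' rejected with an error naming the offending key, so typos never silently
#' fall back to a default.
#'
#' @param path Path to a YAML config file, or `NULL` for defaults only.
#' @param overrides Optional nested list applied after the file (used by the
#'   CLI to let command-line flags override file values).
#' @return The effective nested configuration list.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_config("config file not found: %s", path)
    user <- yaml::read_yaml(path)
    if (!is.list(user)) stop_config("config file %s is not a YAML mapping", path)
    cfg <- merge_config(cfg, user, "")
  }
  if (length(overrides)) cfg <- merge_config(cfg, overrides, "")
  validate_config(cfg)
  cfg
}

merge_config <- function(base, user, prefix) {
  for (key in names(user)) {
    full <- if (nzchar(prefix)) paste0(prefix, ".", key) else key
    if (!key %in% names(base)) {
      stop_config("unknown config key: %s", full)
    }
    if (is.list(base[[key]])) {
      if (!is.list(user[[key]])) {
        stop_config("config key %s must be a mapping", full)
      }
      base[[key]] <- merge_config(base[[key]], user[[key]], full)
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

validate_config <- function(cfg) {
  pp <- cfg$preprocess
  preprocess_params(sg_window = pp$sg_window, sg_order = pp$sg_order,
                    irls_lambda = pp$irls_lambda, irls_p = pp$irls_p,
                    irls_tol = pp$irls_tol, irls_max_iter = pp$irls_max_iter)
  th <- cfg$thresholds
  validation_thresholds(r = th$r, c = th$c, I = th$I)
  if (!cfg$phase$saf_criterion %in% c("distance_to_one", "lowest_mean")) {
    stop_config("phase.saf_criterion must be 'distance_to_one' or 'lowest_mean'")
  }
  if (cfg$phase$alpha <= 0 || cfg$phase$alpha >= 1) {
    stop_config("phase.alpha must be in (0, 1)")
  }
  if (!cfg$io$mz_tol_unit %in% c("ppm", "Th")) {
    stop_config("io.mz_tol_unit must be 'ppm' or 'Th'")
  }
  invisible(cfg)
}
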