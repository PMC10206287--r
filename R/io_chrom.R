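# Reading LC-MS runs, analyte lists and EIC tables; extracting EICs.

#' Construct an analyte specification
#'
#' @param analyte_id Unique identifier for the analyte.
#' @param target_mz Target m/z (Th) of the ion to extract.
#' @param mz_tol Extraction half-window; interpreted per `mz_tol_unit`.
#' @param mz_tol_unit `"ppm"` (converted to Th at `target_mz`) or `"Th"`.
#' @param rt_window Optional `c(lo, hi)` retention-time window in minutes.
#' @param name Human-readable name; defaults to `analyte_id`.
#' @return An object of class `analyte_spec`.
#' @export
analyte_spec <- function(analyte_id, target_mz, mz_tol = 10,
                         mz_tol_unit = c("ppm", "Th"), rt_window = NULL,
                         name = analyte_id) {
  mz_tol_unit <- match.arg(mz_tol_unit)
  if (!is.character(analyte_id) || length(analyte_id) != 1L || !nzchar(analyte_id))
    stop_validation("analyte_id must be a non-empty string")
  if (!is.numeric(target_mz) || target_mz <= 0)
    stop_validation("target_mz must be > 0 (analyte %s)", analyte_id)
  if (!is.numeric(mz_tol) || mz_tol <= 0)
    stop_config("mz_tol must be > 0 (analyte %s)", analyte_id)
  if (!is.null(rt_window)) {
    if (length(rt_window) != 2L || !is.numeric(rt_window) ||
        rt_window[1] >= rt_window[2])
      stop_validation("rt_window must be c(lo, hi) with lo < hi (analyte %s)",
                      analyte_id)
  }
  structure(list(analyte_id = analyte_id, name = name,
                 target_mz = as.numeric(target_mz),
                 mz_tol = as.numeric(mz_tol), mz_tol_unit = mz_tol_unit,
                 rt_window = rt_window),
            class = "analyte_spec")
}

#' Construct an extracted ion chromatogram (EIC)
#'
#' The central signal object: a retention-time/intensity trace for one
#' analyte in one run. Retention time is always in minutes and must be
#' strictly increasing; at least 5 points are required.
#'
#' @param analyte_id Analyte identifier.
#' @param rt Numeric vector of retention times (minutes), strictly increasing.
#' @param intensity Numeric vector of intensities, same length as `rt`.
#' @param run_label,phase_label Optional labels carried through to outputs.
#' @param replicate Optional replicate index.
#' @param is_blank Logical; whether this trace comes from a blank injection.
#' @return An object of class `eic`.
#' @export
eic <- function(analyte_id, rt, intensity, run_label = NA_character_,
                phase_label = NA_character_, replicate = NA_integer_,
                is_blank = FALSE) {
  rt <- as.numeric(rt); intensity <- as.numeric(intensity)
  if (length(rt) != length(intensity))
    stop_validation("rt and intensity must have equal length")
  if (length(rt) < 5L)
    stop_validation("an EIC needs at least 5 points (got %d)", length(rt))
  if (any(!is.finite(rt)) || any(!is.finite(intensity)))
    stop_validation("rt and intensity must be finite")
  if (any(diff(rt) <= 0))
    stop_validation("rt must be strictly increasing")
  structure(list(analyte_id = analyte_id, rt = rt, intensity = intensity,
                 meta = list(run_label = run_label, phase_label = phase_label,
                             replicate = replicate, is_blank = is_blank)),
            class = "eic")
}

#' @export
print.eic <- function(x, ...) {
  cat(sprintf("<eic> %s: %d points, rt %.3f-%.3f min, max intensity %.4g\n",
              x$analyte_id, length(x$rt), x$rt[1], x$rt[length(x$rt)],
              max(x$intensity)))
  invisible(x)
}

#' Read a mass-spectrometry run from mzML or mzXML
#'
#' Reads all spectra of the requested MS level. The file dialect is detected
#' by the parser, not by extension. Retention times are converted to minutes
#' regardless of the file's native unit.
#'
#' @param path Path to an mzML or mzXML file.
#' @param ms_level MS level to retain (default 1).
#' @return An object of class `ms_run` with fields `scans` (a list of
#'   `list(rt, mz, intensity)` with `rt` in minutes, strictly increasing),
#'   `ms_level` and `source_path`.
#' @export
read_ms_run <- function(path, ms_level = 1L) {
  if (!file.exists(path)) stop_parse("file not found: %s", path)
  ms <- tryCatch(mzR::openMSfile(path),
                 error = function(e) stop_parse("cannot parse %s: %s",
                                                path, conditionMessage(e)))
  on.exit(mzR::close(ms))
  hdr <- tryCatch(mzR::header(ms),
                  error = function(e) stop_parse("cannot read spectra from %s: %s",
                                                 path, conditionMessage(e)))
  keep <- which(hdr$msLevel == ms_level)
  if (length(keep) == 0L)
    stop_parse("no spectra at MS level %d in %s", ms_level, path)
  ord <- keep[order(hdr$retentionTime[keep])]
  scans <- lapply(ord, function(i) {
    pk <- mzR::peaks(ms, i)
    list(rt = hdr$retentionTime[i] / 60,   # mzR reports seconds
         mz = pk[, 1], intensity = pk[, 2])
  })
  structure(list(scans = scans, ms_level = as.integer(ms_level),
                 source_path = path),
            class = "ms_run")
}

#' @export
print.ms_run <- function(x, ...) {
  rts <- vapply(x$scans, `[[`, numeric(1), "rt")
  cat(sprintf("<ms_run> %s: %d MS%d scans, rt %.3f-%.3f min\n",
              basename(x$source_path), length(x$scans), x$ms_level,
              min(rts), max(rts)))
  invisible(x)
}

mz_tol_th <- function(spec) {
  if (spec$mz_tol_unit == "ppm") spec$mz_tol * spec$target_mz / 1e6
  else spec$mz_tol
}

#' Extract an ion chromatogram for one analyte
#'
#' For each scan (restricted to the analyte's `rt_window` when given), the
#' EIC intensity is the sum of the intensities of all m/z points within
#' `target_mz` +/- tolerance; a ppm tolerance is converted to Th at the
#' target m/z. Scans with no matching points contribute 0, so the EIC
#' preserves the run's RT grid.
#'
#' @param run An `ms_run` from [read_ms_run()].
#' @param spec An [analyte_spec()].
#' @param run_label,phase_label,replicate,is_blank Metadata forwarded to the
#'   resulting [eic()].
#' @return An [eic()] on the scan RT grid.
#' @export
extract_eic <- function(run, spec, run_label = basename(run$source_path),
                        phase_label = NA_character_, replicate = NA_integer_,
                        is_blank = FALSE) {
  stopifnot(inherits(run, "ms_run"), inherits(spec, "analyte_spec"))
  if (length(run$scans) == 0L) stop_validation("run has no scans")
  tol <- mz_tol_th(spec)
  if (tol <= 0) stop_config("m/z tolerance window has zero width")
  lo <- spec$target_mz - tol
  hi <- spec$target_mz + tol
  rts <- vapply(run$scans, `[[`, numeric(1), "rt")
  keep <- rep(TRUE, length(rts))
  if (!is.null(spec$rt_window)) {
    keep <- rts >= spec$rt_window[1] & rts <= spec$rt_window[2]
  }
  idx <- which(keep)
  if (length(idx) < 5L)
    stop_validation("fewer than 5 scans inside rt_window for analyte %s",
                    spec$analyte_id)
  intensity <- vapply(run$scans[idx], function(s) {
    inwin <- s$mz >= lo & s$mz <= hi
    if (any(inwin)) sum(s$intensity[inwin]) else 0
  }, numeric(1))
  eic(spec$analyte_id, rts[idx], intensity, run_label = run_label,
      phase_label = phase_label, replicate = replicate, is_blank = is_blank)
}

#' Read an analyte list from CSV or TSV
#'
#' Expects a header row with required columns `analyte_id` (or `name`) and
#' `target_mz`; optional columns `mz_tol`, `mz_tol_unit`, `rt_lo`, `rt_hi`.
#' Absent tolerances fall back to the global config default.
#'
#' @param path Path to the CSV/TSV file (dialect chosen by extension:
#'   `.tsv`/`.tab`/`.txt` are tab-separated, all else comma-separated).
#' @param config Configuration list (for `io$mz_tol` and `io$mz_tol_unit`).
#' @return A list of [analyte_spec()] objects.
#' @export
read_analyte_list <- function(path, config = default_config()) {
  if (!file.exists(path)) stop_parse("analyte list not found: %s", path)
  tab <- if (grepl("\\.(tsv|tab|txt)$", path, ignore.case = TRUE))
    read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  else
    read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  cols <- names(tab)
  id_col <- if ("analyte_id" %in% cols) "analyte_id"
            else if ("name" %in% cols) "name" else NA
  missing <- character(0)
  if (is.na(id_col)) missing <- c(missing, "analyte_id (or name)")
  if (!"target_mz" %in% cols) missing <- c(missing, "target_mz")
  if (length(missing))
    stop_config("analyte list %s is missing required column(s): %s",
                path, paste(missing, collapse = ", "))
  ids <- as.character(tab[[id_col]])
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop_validation("duplicate analyte_id in %s: %s", path,
                    paste(unique(dup), collapse = ", "))
  lapply(seq_len(nrow(tab)), function(i) {
    tol <- if ("mz_tol" %in% cols && !is.na(tab$mz_tol[i])) tab$mz_tol[i]
           else config$io$mz_tol
    unit <- if ("mz_tol_unit" %in% cols && !is.na(tab$mz_tol_unit[i]))
      tab$mz_tol_unit[i] else config$io$mz_tol_unit
    win <- NULL
    if (all(c("rt_lo", "rt_hi") %in% cols) &&
        !is.na(tab$rt_lo[i]) && !is.na(tab$rt_hi[i])) {
      win <- c(tab$rt_lo[i], tab$rt_hi[i])
    }
    nm <- if ("name" %in% cols) as.character(tab$name[i]) else ids[i]
    analyte_spec(ids[i], tab$target_mz[i], mz_tol = tol, mz_tol_unit = unit,
                 rt_window = win, name = nm)
  })
}

#' Read an EIC from a two-column CSV
#'
#' A testing/bypass path: loads a pre-extracted chromatogram from a CSV with
#' numeric columns `rt` (minutes) and `intensity`.
#'
#' @param path CSV path.
#' @param analyte_id Analyte identifier to attach.
#' @param ... Metadata forwarded to [eic()].
#' @return An [eic()].
#' @export
read_eic_csv <- function(path, analyte_id = "eic", ...) {
  if (!file.exists(path)) stop_parse("EIC file not found: %s", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("rt", "intensity") %in% names(tab)))
    stop_config("EIC CSV %s must have columns rt,intensity", path)
  eic(analyte_id, tab$rt, tab$intensity, ...)
}

#' Write an EIC to CSV
#'
#' @param x An [eic()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_eic_csv <- function(x, path) {
  stopifnot(inherits(x, "eic"))
  write_table(data.frame(rt = x$rt, intensity = x$intensity), path)
}

#' Write a result table to CSV with stable column order
#'
#' @param rows A data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  write.csv(rows, path, row.names = FALSE, na = "NA")
  invisible(path)
}
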